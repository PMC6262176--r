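# residues used for unit construction; C excluded so cysteine placement is
# fully controlled by cys_positions
.synth_non_cys <- setdiff(.aa_canonical, "C")
.synth_hydrophobic <- c("A", "L", "I", "V", "F", "M", "W")

#' Generate a synthetic tandem-repeat protein with ground truth
#'
#' Builds a multi-domain cysteine-rich repeat protein from a single random
#' unit: cysteines are pinned at `cys_positions` (default a 6-cysteine
#' knottin-like layout in a 35-residue domain), later copies substitute each
#' non-cysteine position independently with probability `divergence`, units
#' are joined by low-complexity G/S linkers, and an optional
#' hydrophobic-biased signal prefix is prepended. Fully deterministic for a
#' given seed.
#'
#' @param seed Integer RNG seed.
#' @param n_domains Number of repeat units (>= 1).
#' @param domain_len Unit length in residues.
#' @param cys_positions 0-based within-unit cysteine offsets.
#' @param divergence Per-non-cysteine-residue substitution probability
#'   between copies, in `[0, 1]`.
#' @param linker_len Linker length between consecutive units (>= 0).
#' @param signal_len Signal-region length (0 for none).
#' @param accession Identifier for the record.
#' @return A one-row tibble: `accession`, `description`, `sequence`,
#'   `reviewed`, `signal_end`, plus ground truth `true_splits` (list-column;
#'   0-based mature positions of the first residue of each later unit),
#'   `true_architecture` (e.g. `"[AA]"`), `true_divergence`, `kind`
#'   (`"screp"`).
#' @export
make_screp <- function(seed, n_domains = 2L, domain_len = 35L,
                       cys_positions = c(2L, 9L, 16L, 21L, 27L, 32L),
                       divergence = 0, linker_len = 5L, signal_len = 0L,
                       accession = paste0("SYN", seed)) {
  stopifnot(n_domains >= 1, domain_len >= 1, linker_len >= 0, signal_len >= 0,
            divergence >= 0, divergence <= 1,
            all(cys_positions >= 0), all(cys_positions < domain_len))
  with_seed(seed, {
    unit <- sample(.synth_non_cys, domain_len, replace = TRUE)
    unit[cys_positions + 1L] <- "C"
    non_cys_idx <- setdiff(seq_len(domain_len), cys_positions + 1L)
    copies <- list(unit)
    if (n_domains > 1) {
      for (d in 2:n_domains) {
        cp <- unit
        if (divergence > 0) {
          mut <- non_cys_idx[stats::runif(length(non_cys_idx)) < divergence]
          for (j in mut) {
            cp[j] <- sample(setdiff(.synth_non_cys, cp[j]), 1L)
          }
        }
        copies[[d]] <- cp
      }
    }
    linkers <- replicate(max(n_domains - 1L, 0L),
                         paste(sample(c("G", "S"), linker_len, replace = TRUE),
                               collapse = ""))
    signal <- if (signal_len > 0) {
      paste(c("M", sample(.synth_hydrophobic, signal_len - 1L, replace = TRUE)),
            collapse = "")
    } else ""
    parts <- character(0)
    for (d in seq_len(n_domains)) {
      parts <- c(parts, paste(copies[[d]], collapse = ""))
      if (d < n_domains) parts <- c(parts, linkers[d])
    }
    mature <- paste(parts, collapse = "")
    sequence <- paste0(signal, mature)
    if (nchar(mature) > 500L) {
      warning("synthetic layout exceeds 500 mature residues", call. = FALSE)
    }
    true_splits <- if (n_domains > 1) {
      (domain_len + linker_len) * seq_len(n_domains - 1L)
    } else integer(0)
    unit_starts <- (domain_len + linker_len) * (seq_len(n_domains) - 1L)
    tibble::tibble(
      accession = accession,
      description = paste0("synthetic repeat protein n_domains=", n_domains,
                           " divergence=", divergence),
      sequence = sequence,
      reviewed = NA,
      signal_end = if (signal_len > 0) signal_len else NA_integer_,
      true_splits = list(as.integer(true_splits)),
      true_units = list(tibble::tibble(start = as.integer(unit_starts + 1L),
                                       stop = as.integer(unit_starts + domain_len))),
      true_architecture = paste0("[", paste(rep("A", n_domains), collapse = ""), "]"),
      true_divergence = divergence,
      kind = "screp"
    )
  })
}

#' Generate a non-repeat decoy record
#'
#' Three decoy classes mimic the main false-positive sources the refinement
#' stage deals with: `shuffled` permutes a synthetic repeat protein's mature
#' residues (destroying tandem structure while preserving length and
#' composition), `cxxch_heme` emulates a cytochrome-c-like protein (~3%
#' cysteine arranged as CxxCH heme-binding motifs, no repeats), and
#' `low_cys` carries only 2-3 cysteines and fails the scan prefilter.
#'
#' @param seed Integer RNG seed.
#' @param kind One of `"shuffled"`, `"cxxch_heme"`, `"low_cys"`.
#' @param length Decoy length for the non-shuffled kinds.
#' @param accession Identifier for the record.
#' @param ... For `kind = "shuffled"`, passed on to [make_screp()] for the
#'   source record.
#' @return A one-row tibble shaped like [make_screp()]'s output with
#'   `kind` set to the decoy class and empty ground truth.
#' @export
make_decoy <- function(seed, kind = c("shuffled", "cxxch_heme", "low_cys"),
                       length = 150L, accession = paste0("DEC", seed), ...) {
  kind <- match.arg(kind)
  rec <- with_seed(seed + 1000003L, {
    if (kind == "shuffled") {
      src <- make_screp(seed, ...)
      chars <- strsplit(src$sequence, "")[[1]]
      paste(sample(chars), collapse = "")
    } else if (kind == "cxxch_heme") {
      chars <- sample(.synth_non_cys, length, replace = TRUE)
      # two CxxCH motifs ~ 4 Cys; density stays in the 2-4% band
      for (at in c(10L, floor(length / 2) + 7L)) {
        chars[at] <- "C"; chars[at + 3L] <- "C"; chars[at + 4L] <- "H"
      }
      paste(chars, collapse = "")
    } else {
      chars <- sample(.synth_non_cys, 80L, replace = TRUE)
      chars[sample(80L, sample(2:3, 1L))] <- "C"
      paste(chars, collapse = "")
    }
  })
  tibble::tibble(
    accession = accession,
    description = paste0("synthetic decoy kind=", kind),
    sequence = rec,
    reviewed = NA,
    signal_end = NA_integer_,
    true_splits = list(integer(0)),
    true_units = list(tibble::tibble(start = integer(0), stop = integer(0))),
    true_architecture = "",
    true_divergence = NA_real_,
    kind = kind
  )
}

#' Generate a mixed benchmark with ground truth
#'
#' Builds `n_pos` synthetic two-domain repeat proteins whose divergence
#' cycles through `divergence_grid`, plus `n_neg` shuffled decoys, and
#' optionally writes them to disk as `fixtures.fa`, `truth.tsv`,
#' `signals.tsv` and a miniature InterProScan-style `domains.tsv` (two
#' same-type domain rows per positive, at the true unit coordinates).
#'
#' @param seed Integer RNG seed; record seeds are derived from it.
#' @param n_pos,n_neg Numbers of positive and decoy records.
#' @param dir Output directory, or `NULL` to skip writing.
#' @param divergence_grid Divergence levels cycled across positives.
#' @param signal_len Signal length for positive records.
#' @param ... Passed to [make_screp()] for the positives.
#' @return A list with `records` (tibble of all records, positives first)
#'   and `truth` (tibble: `accession`, `kind`, `divergence`, `true_split`,
#'   `true_architecture`), plus `paths` when `dir` is given.
#' @export
make_benchmark <- function(seed, n_pos = 20L, n_neg = 20L, dir = NULL,
                           divergence_grid = c(0, 0.1, 0.2, 0.3, 0.4),
                           signal_len = 0L, ...) {
  divs <- rep_len(divergence_grid, n_pos)
  pos <- purrr::map(seq_len(n_pos), function(i) {
    make_screp(seed + i, divergence = divs[i], signal_len = signal_len,
               accession = sprintf("POS%03d", i), ...)
  })
  neg <- purrr::map(seq_len(n_neg), function(i) {
    make_decoy(seed + 50000L + i, kind = "shuffled",
               accession = sprintf("NEG%03d", i), ...)
  })
  records <- dplyr::bind_rows(c(pos, neg))
  truth <- tibble::tibble(
    accession = records$accession,
    kind = records$kind,
    divergence = records$true_divergence,
    true_split = vapply(records$true_splits,
                        function(s) if (length(s)) s[1] else NA_integer_,
                        integer(1)),
    true_architecture = records$true_architecture
  )
  out <- list(records = records, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, "fixtures.fa")
    write_fasta(records, fa)
    truth_path <- file.path(dir, "truth.tsv")
    write_screp_tsv(truth, truth_path)
    sig <- records[!is.na(records$signal_end),
                   c("accession", "signal_end"), drop = FALSE]
    sig_path <- file.path(dir, "signals.tsv")
    write_screp_tsv(sig, sig_path)
    dom_path <- file.path(dir, "domains.tsv")
    writeLines(benchmark_domain_rows(records), dom_path, useBytes = TRUE)
    out$paths <- c(fasta = fa, truth = truth_path, signals = sig_path,
                   domains = dom_path)
  }
  out
}

# miniature InterProScan-style rows (13 columns) for the positive records:
# one SYNDOM row per true unit, on mature coordinates
benchmark_domain_rows <- function(records) {
  rows <- character(0)
  for (i in seq_len(nrow(records))) {
    if (records$kind[i] != "screp") next
    units <- records$true_units[[i]]
    sig <- records$signal_end[i]
    offset <- if (is.na(sig)) 0L else sig
    mature_len <- nchar(records$sequence[i]) - offset
    for (d in seq_len(nrow(units))) {
      rows <- c(rows, paste(
        records$accession[i], "md5", mature_len, "SYNDB", "SYNDOM001",
        "Synthetic knottin-like repeat unit", units$start[d], units$stop[d],
        "0.0", "T", "2026-01-01", "IPRSYN001", "Synthetic repeat unit",
        sep = "\t"))
    }
  }
  rows
}
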