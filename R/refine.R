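#' Cysteine density of a sequence
#'
#' Percentage of residues that are cysteine (`C`; selenocysteine `U` does
#' not count), computed on the mature sequence. Characteristic per domain
#' type, so it doubles as a coarse clustering axis: heme-coordinating and
#' redox-active proteins concentrate in the 2-3% band.
#'
#' @param sequence Amino-acid string(s).
#' @return Numeric vector of percentages in `[0, 100]`.
#' @examples
#' cysteine_density("CCCCAAAAAA") # 40
#' @export
cysteine_density <- function(sequence) {
  100 * cysteine_count(sequence) / nchar(sequence)
}

#' Cysteine-density histogram
#'
#' Bins record densities into half-open intervals `[k*w, (k+1)*w)` of width
#' `w` percent. Counts always sum to the number of records.
#'
#' @param records A records tibble; the `mature` column is used when
#'   present, else `sequence`.
#' @param bin_width Bin width in percentage points.
#' @return A tibble with columns `bin_lower_pct` and `count`, ascending;
#'   empty input gives an empty table.
#' @export
density_histogram <- function(records, bin_width = 1.0) {
  stopifnot(bin_width > 0)
  if (nrow(records) == 0L) {
    return(tibble::tibble(bin_lower_pct = numeric(0), count = integer(0)))
  }
  d <- cysteine_density(records[[seq_column(records)]])
  bin <- floor(d / bin_width) * bin_width
  dplyr::count(tibble::tibble(bin_lower_pct = bin), .data$bin_lower_pct,
               name = "count")
}

#' Exclude annotated non-repeat cysteine-rich classes
#'
#' Flags records whose domain annotations identify cysteine usage that is
#' catalytic or metal-coordinating rather than disulfide-forming — by
#' default cytochrome c (heme-binding CxxCH cysteines) and thioredoxin
#' (redox-active dithiol) — which the self-alignment scan picks up without
#' them being true disulfide-rich repeats. A record is removed iff any of
#' its annotations matches an exclusion term (case-insensitive substring of
#' the signature or InterPro description) or an exclusion id (exact match);
#' unannotated records are kept.
#'
#' @param records A records tibble.
#' @param annotations A domain-annotation tibble
#'   ([read_interproscan_tsv()]).
#' @param exclusion_terms Case-insensitive substrings matched against
#'   descriptions.
#' @param exclusion_ids Signature/InterPro accessions matched exactly.
#' @return `records` with logical `kept` and character `exclusion_reason`
#'   (`NA` for kept rows) columns appended.
#' @export
exclude_non_screps <- function(records, annotations,
                               exclusion_terms = c("cytochrome c", "thioredoxin"),
                               exclusion_ids = character()) {
  assert_records(records)
  reason <- rep(NA_character_, nrow(records))
  if (nrow(annotations) > 0L && (length(exclusion_terms) || length(exclusion_ids))) {
    desc <- tolower(paste(annotations$signature_desc, annotations$interpro_desc))
    hit_term <- rep(NA_character_, nrow(annotations))
    for (term in exclusion_terms) {
      m <- is.na(hit_term) & grepl(tolower(term), desc, fixed = TRUE)
      hit_term[m] <- paste0("term:", term)
    }
    id_hit <- annotations$signature_id %in% exclusion_ids |
      annotations$interpro_id %in% exclusion_ids
    hit_term[is.na(hit_term) & id_hit] <- paste0(
      "id:", ifelse(annotations$signature_id[is.na(hit_term) & id_hit] %in% exclusion_ids,
                    annotations$signature_id[is.na(hit_term) & id_hit],
                    annotations$interpro_id[is.na(hit_term) & id_hit]))
    flagged <- annotations[!is.na(hit_term), , drop = FALSE]
    flagged_reason <- hit_term[!is.na(hit_term)]
    first <- !duplicated(flagged$accession)
    idx <- match(records$accession, flagged$accession[first])
    reason <- flagged_reason[first][idx]
  }
  records$kept <- is.na(reason)
  records$exclusion_reason <- reason
  records
}

#' Greedy identity-threshold redundancy clustering
#'
#' Re-implements the greedy incremental strategy of cd-hit at desk scale:
#' sequences are sorted by length descending (ties: accession ascending) and
#' each joins the first existing cluster whose representative it matches at
#' identity >= `identity`, where identity is the number of identical aligned
#' columns of the global alignment divided by the length of the shorter
#' sequence; otherwise it founds a new cluster. Representatives are
#' therefore the longest member of each cluster. No k-mer prefilter is used,
#' so clusters can only be equal to or coarser than cd-hit's.
#'
#' @param records A records tibble; the `mature` column is used when present.
#' @param identity Identity threshold in `(0, 1]`; default 0.99.
#' @param scheme A [scoring_scheme()] for the global alignments.
#' @return A tibble with one row per input record: `accession`, `cluster`
#'   (integer id in founding order), `representative` (accession),
#'   `is_representative`, `identity_to_rep`.
#' @export
cluster_redundant <- function(records, identity = 0.99,
                              scheme = scoring_scheme()) {
  assert_records(records)
  stopifnot(identity > 0, identity <= 1)
  col <- seq_column(records)
  ord <- order(-nchar(records[[col]]), records$accession)
  acc <- records$accession[ord]
  seqs <- records[[col]][ord]
  rep_acc <- character(0)
  rep_seq <- character(0)
  cluster <- integer(length(acc))
  ident <- numeric(length(acc))
  for (i in seq_along(seqs)) {
    assigned <- FALSE
    for (ci in seq_along(rep_seq)) {
      pid <- pair_identity(seqs[i], rep_seq[ci], scheme)
      if (pid >= identity) {
        cluster[i] <- ci
        ident[i] <- pid
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_acc <- c(rep_acc, acc[i])
      rep_seq <- c(rep_seq, seqs[i])
      cluster[i] <- length(rep_acc)
      ident[i] <- 1
    }
  }
  out <- tibble::tibble(
    accession = acc, cluster = cluster,
    representative = rep_acc[cluster],
    is_representative = acc == rep_acc[cluster],
    identity_to_rep = ident
  )
  out[order(match(out$accession, records$accession)), ]
}

# identity = identical aligned columns / length of the shorter sequence
pair_identity <- function(a, b, scheme) {
  if (a == b) return(1)
  g <- global_align(a, b, scheme)
  g$n_match / min(nchar(a), nchar(b))
}
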