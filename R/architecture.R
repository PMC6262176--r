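#' Build a domain architecture from annotations
#'
#' Orders a record's domain annotations along the sequence, resolves
#' overlaps, assigns each distinct domain type a letter (`A`, `B`, ... in
#' order of first appearance) and classifies the repeat structure:
#' `pure` when there are >= 2 units all of one type (`[AA]`, `[AAA]`),
#' `combinatorial` when some type repeats alongside at least one unit of
#' another type (`[ABB]`, `[BAAC]`), and `non_repeat` otherwise.
#'
#' Domain type identity is the InterPro accession when present, else the
#' signature accession. Overlapping annotations of the same type are merged
#' when the overlap exceeds half of the shorter interval; across types the
#' earlier-listed annotation wins under the same overlap rule.
#'
#' @param sequence The record's (mature) amino-acid string.
#' @param annotations Domain-annotation rows for this record
#'   ([read_interproscan_tsv()]).
#' @param accession Identifier carried into the result.
#' @return A list of class `screp_architecture` with elements `accession`,
#'   `domain_string` (e.g. `"[AA]"`), `repeat_class`, `units` (tibble:
#'   `type_id`, `letter`, `start`, `stop`, `subsequence`; 1-based inclusive
#'   coordinates), `n_units`, `n_types`.
#' @export
build_architecture <- function(sequence, annotations, accession = "seq") {
  stopifnot(length(sequence) == 1L)
  if (nrow(annotations) > 0L) {
    type_id <- ifelse(nzchar(annotations$interpro_id),
                      annotations$interpro_id, annotations$signature_id)
    units <- tibble::tibble(type_id = type_id,
                            start = annotations$start,
                            stop = annotations$stop)
    units <- units[order(units$start, units$stop), , drop = FALSE]
    units <- resolve_overlaps(units)
  } else {
    units <- tibble::tibble(type_id = character(), start = integer(),
                            stop = integer())
  }
  first_seen <- unique(units$type_id)
  if (length(first_seen) > length(LETTERS)) {
    stop("more than 26 distinct domain types in one record", call. = FALSE)
  }
  units$letter <- LETTERS[match(units$type_id, first_seen)]
  units$subsequence <- substr(rep(sequence, nrow(units)), units$start, units$stop)
  counts <- table(units$type_id)
  repeat_class <-
    if (nrow(units) >= 2 && length(counts) == 1) "pure"
    else if (any(counts >= 2) && length(counts) >= 2) "combinatorial"
    else "non_repeat"
  structure(
    list(accession = accession,
         domain_string = paste0("[", paste(units$letter, collapse = ""), "]"),
         repeat_class = repeat_class,
         units = units[, c("type_id", "letter", "start", "stop", "subsequence")],
         n_units = nrow(units), n_types = length(counts)),
    class = "screp_architecture"
  )
}

# merge same-type annotations overlapping > 50% of the shorter interval;
# across types the earlier-listed annotation wins under the same rule
resolve_overlaps <- function(units) {
  if (nrow(units) <= 1L) return(units)
  kept <- units[1, , drop = FALSE]
  for (i in 2:nrow(units)) {
    cur <- units[i, , drop = FALSE]
    last <- kept[nrow(kept), , drop = FALSE]
    ov <- min(last$stop, cur$stop) - max(last$start, cur$start) + 1L
    shorter <- min(last$stop - last$start, cur$stop - cur$start) + 1L
    if (ov > shorter / 2) {
      if (cur$type_id == last$type_id) {
        kept$stop[nrow(kept)] <- max(last$stop, cur$stop)
      }
      # different type: drop the later-listed annotation
    } else {
      kept <- dplyr::bind_rows(kept, cur)
    }
  }
  kept
}

#' @export
print.screp_architecture <- function(x, ...) {
  cat("<architecture> ", x$accession, " ", x$domain_string, " (",
      x$repeat_class, ", ", x$n_units, " unit(s))\n", sep = "")
  invisible(x)
}

#' Repeat purity of an architecture
#'
#' Mean pairwise global-alignment sequence identity (percent, over the full
#' alignment length including gap columns) between the repeating units of
#' the most-copied domain type; ties between types go to the type whose
#' first unit starts earliest.
#'
#' @param arch A `screp_architecture` (or its `units` tibble).
#' @param scheme A [scoring_scheme()].
#' @return A single percentage in `[0, 100]`. Errors with
#'   `"purity undefined"` when no type has >= 2 units.
#' @export
repeat_purity <- function(arch, scheme = scoring_scheme()) {
  units <- if (inherits(arch, "screp_architecture")) arch$units else arch
  counts <- table(units$type_id)
  if (!any(counts >= 2)) stop("purity undefined: no repeated domain type", call. = FALSE)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1) {
    firsts <- vapply(top, function(t) min(units$start[units$type_id == t]), numeric(1))
    top <- top[which.min(firsts)]
  }
  seqs <- units$subsequence[units$type_id == top]
  pairs <- utils::combn(length(seqs), 2)
  ids <- apply(pairs, 2, function(p) {
    if (seqs[p[1]] == seqs[p[2]]) return(100)
    global_align(seqs[p[1]], seqs[p[2]], scheme)$identity_pct
  })
  mean(ids)
}

#' Build architectures for a set of records
#'
#' @param records A records tibble; the `mature` column is used when
#'   present.
#' @param annotations Domain annotations for the set.
#' @param scheme A [scoring_scheme()] for purity; purity is `NA` where
#'   undefined (no repeated type).
#' @return A tibble of class `screp_architectures`: `accession`,
#'   `domain_string`, `repeat_class`, `n_units`, `n_types`, `purity_pct`
#'   and an `arch` list-column holding each `screp_architecture`.
#' @export
build_architectures <- function(records, annotations,
                                scheme = scoring_scheme()) {
  assert_records(records)
  col <- seq_column(records)
  archs <- purrr::map2(records[[col]], records$accession, function(s, a) {
    build_architecture(s, annotations[annotations$accession == a, , drop = FALSE],
                       accession = a)
  })
  purity <- vapply(archs, function(a) {
    if (any(table(a$units$type_id) >= 2)) repeat_purity(a, scheme) else NA_real_
  }, numeric(1))
  out <- tibble::tibble(
    accession = records$accession,
    domain_string = vapply(archs, `[[`, character(1), "domain_string"),
    repeat_class = vapply(archs, `[[`, character(1), "repeat_class"),
    n_units = vapply(archs, `[[`, integer(1), "n_units"),
    n_types = vapply(archs, `[[`, integer(1), "n_types"),
    purity_pct = purity,
    arch = archs
  )
  class(out) <- c("screp_architectures", class(out))
  out
}

#' Domain-type frequency report
#'
#' For each domain type: the number of proteins containing at least one
#' unit, and the mean copy number among those proteins. Sorted by
#' `n_proteins` descending.
#'
#' @param architectures A [build_architectures()] result.
#' @return A tibble with columns `domain_type`, `n_proteins`,
#'   `mean_copies_per_protein`.
#' @export
domain_frequency_report <- function(architectures) {
  per <- purrr::map(architectures$arch, function(a) {
    if (nrow(a$units) == 0L) return(NULL)
    dplyr::count(a$units, .data$type_id, name = "copies")
  })
  flat <- dplyr::bind_rows(per)
  if (nrow(flat) == 0L) {
    return(tibble::tibble(domain_type = character(), n_proteins = integer(),
                          mean_copies_per_protein = numeric()))
  }
  out <- dplyr::summarise(dplyr::group_by(flat, domain_type = .data$type_id),
                          n_proteins = dplyr::n(),
                          mean_copies_per_protein = mean(.data$copies),
                          .groups = "drop")
  dplyr::arrange(out, dplyr::desc(.data$n_proteins), .data$domain_type)
}
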