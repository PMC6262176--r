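#' Screen candidates against a reference toxin set
#'
#' All-vs-all exact local alignment of candidate mature sequences against a
#' reference FASTA (e.g. a Tox-Prot or ion-channel-impairing-toxin export).
#' E-values use `m` = query length and `n` = total residues in the reference
#' set. A hit passes when `evalue <= evalue_cutoff` and
#' `bit_score > bit_cutoff` (both applied jointly; defaults 1e-6 and 35).
#'
#' @param screps Candidate records tibble; the `mature` column is used when
#'   present.
#' @param reference Reference records tibble (non-empty).
#' @param evalue_cutoff Maximum E-value for a passing hit.
#' @param bit_cutoff Bit-score threshold, strict (`>`).
#' @param scheme A [scoring_scheme()].
#' @param keep_all Keep non-passing alignments too (with `passes = FALSE`).
#' @param best_only Keep only each query's lowest-E-value hit.
#' @return A tibble of class `screp_hits`, sorted by `(screp_id, evalue)`:
#'   `screp_id`, `toxin_id`, `raw_score`, `bit_score`, `evalue`,
#'   `identity_pct`, `gap_openings`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `passes`.
#' @export
homology_screen <- function(screps, reference, evalue_cutoff = 1e-6,
                            bit_cutoff = 35, scheme = scoring_scheme(),
                            keep_all = FALSE, best_only = FALSE) {
  assert_records(screps, "screps")
  assert_records(reference, "reference")
  if (nrow(reference) == 0L) stop("empty reference set", call. = FALSE)
  qcol <- seq_column(screps)
  rcol <- seq_column(reference)
  search_space <- sum(nchar(reference[[rcol]]))
  rows <- vector("list", nrow(screps))
  for (i in seq_len(nrow(screps))) {
    q <- screps[[qcol]][i]
    # substitution matrices are symmetric, so scoring references against the
    # query in one vectorized call gives the query-vs-reference scores
    raw <- alignment_scores(reference[[rcol]], q, scheme, type = "local")
    stats <- evalue(raw, m = nchar(q), n = search_space, scheme)
    passes <- stats$evalue <= evalue_cutoff & stats$bit_score > bit_cutoff
    want <- if (keep_all) seq_along(raw) else which(passes)
    if (length(want) == 0L) next
    hits <- purrr::map(want, function(j) {
      aln <- local_align(q, reference[[rcol]][j], scheme,
                         query_id = screps$accession[i],
                         subject_id = reference$accession[j],
                         m = nchar(q), n = search_space)
      aln$passes <- passes[j]
      aln
    })
    rows[[i]] <- dplyr::bind_rows(hits)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      query_id = character(), subject_id = character(),
      raw_score = integer(), bit_score = numeric(), evalue = numeric(),
      identity_pct = numeric(), gap_openings = integer(),
      q_start = integer(), q_end = integer(),
      s_start = integer(), s_end = integer(),
      n_match = integer(), aln_length = integer(), passes = logical()
    )
  }
  out <- dplyr::rename(out, screp_id = "query_id", toxin_id = "subject_id")
  out <- dplyr::select(out, -"n_match", -"aln_length")
  out <- dplyr::arrange(out, .data$screp_id, .data$evalue, .data$toxin_id)
  if (best_only && nrow(out) > 0L) {
    out <- dplyr::slice_head(dplyr::group_by(out, .data$screp_id), n = 1L)
    out <- dplyr::ungroup(out)
  }
  class(out) <- c("screp_hits", class(out))
  out
}

#' Records present in both candidate and reference sets
#'
#' Reports shared accessions, and byte-identical sequences carried under
#' distinct accessions (both ids reported).
#'
#' @param screps,reference Records tibbles.
#' @return A tibble with columns `screp_accession`, `reference_accession`,
#'   `match_type` (`"accession"` or `"sequence"`).
#' @export
overlap_report <- function(screps, reference) {
  qcol <- seq_column(screps)
  rcol <- seq_column(reference)
  by_acc <- intersect(screps$accession, reference$accession)
  acc_rows <- tibble::tibble(screp_accession = by_acc,
                             reference_accession = by_acc,
                             match_type = rep("accession", length(by_acc)))
  idx <- match(screps[[qcol]], reference[[rcol]])
  seq_hit <- !is.na(idx) & !(screps$accession %in% by_acc)
  seq_rows <- tibble::tibble(
    screp_accession = screps$accession[seq_hit],
    reference_accession = reference$accession[idx[seq_hit]],
    match_type = rep("sequence", sum(seq_hit))
  )
  dplyr::bind_rows(acc_rows, seq_rows)
}

#' Taxonomic distribution of screening hits
#'
#' Counts distinct candidate sequences with passing hits per taxon and flags
#' taxa that also occur in the reference set. Candidates without a taxonomy
#' entry are tallied under `"unannotated"`.
#'
#' @param hits A [homology_screen()] result.
#' @param screp_tax Tibble mapping `accession` to `taxon` for candidates.
#' @param ref_tax Tibble mapping `accession` to `taxon` for the reference
#'   set (or a character vector of reference taxa).
#' @return A tibble with columns `taxon`, `n_screps`,
#'   `shared_with_reference`, sorted by `n_screps` descending.
#' @export
taxonomy_overlap <- function(hits, screp_tax, ref_tax) {
  ids <- unique(hits$screp_id[hits$passes])
  if (is.data.frame(ref_tax)) ref_tax <- ref_tax$taxon
  taxa <- screp_tax$taxon[match(ids, screp_tax$accession)]
  taxa[is.na(taxa) | taxa == ""] <- "unannotated"
  if (length(ids) == 0L) {
    return(tibble::tibble(taxon = character(), n_screps = integer(),
                          shared_with_reference = logical()))
  }
  out <- dplyr::count(tibble::tibble(taxon = taxa), .data$taxon,
                      name = "n_screps")
  out$shared_with_reference <- out$taxon %in% ref_tax
  dplyr::arrange(out, dplyr::desc(.data$n_screps), .data$taxon)
}
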