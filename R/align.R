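#' Pairwise local alignment (Smith-Waterman, affine gaps)
#'
#' Computes the optimal local alignment of two amino-acid sequences under the
#' scheme's substitution matrix and affine gap model, together with
#' Karlin-Altschul bit score and E-value. This is the exact-alignment
#' counterpart of a `blastp` comparison: scores are deterministic optima, so
#' they are never lower than what a heuristic search would report.
#'
#' The empty alignment (raw score 0) is a legal result when no residue pair
#' scores positively; it is reported with zero-width coordinate ranges.
#'
#' @param query,subject Non-empty amino-acid strings.
#' @param scheme A [scoring_scheme()].
#' @param query_id,subject_id Identifiers carried into the result.
#' @param m,n Query length and search-space residue count used for the
#'   E-value; default to the lengths of the two input sequences.
#' @return A one-row tibble with columns `query_id`, `subject_id`,
#'   `raw_score`, `bit_score`, `evalue`, `identity_pct` (identical columns /
#'   alignment length including gap columns, as a percentage),
#'   `gap_openings`, and 0-based half-open coordinates `q_start`, `q_end`,
#'   `s_start`, `s_end`.
#' @examples
#' local_align("CWC", "CWC")$raw_score # 9 + 11 + 9 = 29
#' @export
local_align <- function(query, subject, scheme = scoring_scheme(),
                        query_id = "query", subject_id = "subject",
                        m = NULL, n = NULL) {
  align_pair(query, subject, scheme, "local", query_id, subject_id, m, n)
}

#' Pairwise global alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal end-to-end alignment under the same affine-gap model as
#' [local_align()]. Used for repeat-purity and redundancy-clustering
#' identities, where both sequences are pre-delimited units. `identity_pct`
#' is computed over the full alignment length, gap columns included.
#'
#' @inheritParams local_align
#' @return A one-row tibble shaped like [local_align()]'s result; the
#'   coordinate ranges span both full sequences and `raw_score` may be
#'   negative. The extra column `n_match` gives the count of identical
#'   aligned columns and `aln_length` the alignment length.
#' @export
global_align <- function(query, subject, scheme = scoring_scheme(),
                         query_id = "query", subject_id = "subject") {
  align_pair(query, subject, scheme, "global", query_id, subject_id, NULL, NULL)
}

align_pair <- function(query, subject, scheme, type, query_id, subject_id, m, n) {
  if (!nzchar(query) || !nzchar(subject)) {
    stop("cannot align an empty sequence", call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = query, subject = subject, type = type,
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend
  )
  raw <- BiocGenerics::score(pa)
  if (type == "local" && raw <= 0) {
    # no positive-scoring cell: the optimum is the empty alignment
    stats <- evalue(0L, m %||% nchar(query), n %||% nchar(subject), scheme)
    return(tibble::tibble(
      query_id = query_id, subject_id = subject_id,
      raw_score = 0L, bit_score = stats$bit_score, evalue = stats$evalue,
      identity_pct = 0, gap_openings = 0L,
      q_start = 0L, q_end = 0L, s_start = 0L, s_end = 0L,
      n_match = 0L, aln_length = 0L
    ))
  }
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  cols_p <- strsplit(ap, "")[[1]]
  cols_s <- strsplit(as_, "")[[1]]
  alen <- length(cols_p)
  nmatch <- sum(cols_p == cols_s & cols_p != "-")
  gap_openings <- count_gap_runs(cols_p) + count_gap_runs(cols_s)
  raw <- as.integer(round(raw))
  stats <- evalue(max(raw, 0L), m %||% nchar(query), n %||% nchar(subject), scheme)
  p <- Biostrings::pattern(pa)
  s <- Biostrings::subject(pa)
  tibble::tibble(
    query_id = query_id, subject_id = subject_id,
    raw_score = raw, bit_score = stats$bit_score, evalue = stats$evalue,
    identity_pct = 100 * nmatch / alen, gap_openings = gap_openings,
    q_start = BiocGenerics::start(p) - 1L,
    q_end = BiocGenerics::start(p) - 1L + nchar(gsub("-", "", ap, fixed = TRUE)),
    s_start = BiocGenerics::start(s) - 1L,
    s_end = BiocGenerics::start(s) - 1L + nchar(gsub("-", "", as_, fixed = TRUE)),
    n_match = nmatch, aln_length = alen
  )
}

count_gap_runs <- function(chars) {
  gap <- chars == "-"
  sum(gap & !c(FALSE, gap[-length(gap)]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Raw local/global alignment scores only
#'
#' Fast path used by the bisection scan and homology screen: returns just the
#' optimal score for each query against one subject (or one query against
#' many subjects), skipping traceback.
#'
#' @param queries Character vector of amino-acid strings.
#' @param subject A single amino-acid string.
#' @param scheme A [scoring_scheme()].
#' @param type `"local"` or `"global"`.
#' @return Numeric vector of optimal scores; local scores are clamped at 0
#'   (the empty alignment).
#' @export
alignment_scores <- function(queries, subject, scheme = scoring_scheme(),
                             type = "local") {
  if (any(!nzchar(queries)) || !nzchar(subject)) {
    stop("cannot align an empty sequence", call. = FALSE)
  }
  s <- Biostrings::pairwiseAlignment(
    pattern = queries, subject = subject, type = type,
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    scoreOnly = TRUE
  )
  if (type == "local") pmax(s, 0) else s
}

#' Karlin-Altschul bit score and E-value
#'
#' Converts a raw alignment score into a bit score,
#' `bit = (lambda * S - ln K) / ln 2`, and an E-value over an `m x n` search
#' space, `E = m * n * 2^-bit`.
#'
#' @param raw_score Non-negative raw alignment score(s).
#' @param m Query length in residues.
#' @param n Search-space size: total residues in the subject database.
#' @param scheme A [scoring_scheme()] supplying lambda and K.
#' @return A tibble with columns `bit_score` and `evalue`.
#' @examples
#' evalue(100, 100, 100) # ~43.1 bits, E ~ 1e-9
#' @export
evalue <- function(raw_score, m, n, scheme = scoring_scheme()) {
  stopifnot(all(raw_score >= 0), m >= 1, n >= 1)
  bit <- (scheme$lambda * raw_score - log(scheme$k)) / log(2)
  tibble::tibble(bit_score = bit, evalue = m * n * 2^(-bit))
}
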