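#' Configuration for the tandem-repeat bisection scan
#'
#' The scan considers mature sequences of 20-500 residues (inclusive) with at
#' least 4 cysteines — the minimum for one disulfide bond per domain in a
#' two-domain protein — and slides a division site along the sequence in
#' steps of `step_n` residues, locally aligning the prefix against the
#' suffix at each site. A self-alignment with raw score strictly greater
#' than `strong_threshold` (default 30) is a strong tandem-repeat call;
#' a positive score at or below it is weak.
#'
#' @param min_len,max_len Inclusive mature-length bounds.
#' @param min_cys Minimum cysteine count (selenocysteine `U` is not counted).
#' @param step_n Division-site increment in residues.
#' @param strong_threshold Raw-score threshold; strictly greater is strong.
#' @param scheme A [scoring_scheme()].
#' @return A list of class `spa_config`.
#' @export
spa_config <- function(min_len = 20L, max_len = 500L, min_cys = 4L,
                       step_n = 10L, strong_threshold = 30L,
                       scheme = scoring_scheme()) {
  stopifnot(min_len > 0, min_len <= max_len, min_cys >= 0,
            step_n >= 1, strong_threshold >= 0)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 min_cys = as.integer(min_cys), step_n = as.integer(step_n),
                 strong_threshold = as.integer(strong_threshold),
                 scheme = scheme),
            class = "spa_config")
}

#' Count cysteine residues
#'
#' Counts `C` only; selenocysteine (`U`) is not a cysteine here.
#'
#' @param sequence Amino-acid string(s).
#' @return Integer vector of cysteine counts.
#' @export
cysteine_count <- function(sequence) {
  stringr::str_count(sequence, stringr::fixed("C"))
}

#' Prefilter a mature sequence for the bisection scan
#'
#' @param sequence Mature amino-acid string(s).
#' @param config A [spa_config()].
#' @return Character vector: one of `"pass"`, `"too_short"`, `"too_long"`,
#'   `"too_few_cys"` per sequence. Length bounds are inclusive and checked
#'   before the cysteine count.
#' @export
spa_prefilter <- function(sequence, config = spa_config()) {
  len <- nchar(sequence)
  dplyr::case_when(
    len < config$min_len ~ "too_short",
    len > config$max_len ~ "too_long",
    cysteine_count(sequence) < config$min_cys ~ "too_few_cys",
    TRUE ~ "pass"
  )
}

#' Division sites for a sequence length
#'
#' All multiples of `step_n` that leave both segments at least `step_n`
#' residues long, in ascending order. A sequence shorter than `2 * step_n`
#' has no admissible site.
#'
#' @param length Mature sequence length in residues.
#' @param config A [spa_config()].
#' @return Integer vector of split positions (prefix lengths).
#' @examples
#' spa_split_points(60) # 10 20 30 40 50
#' @export
spa_split_points <- function(length, config = spa_config()) {
  n <- config$step_n
  hi <- length - n
  if (hi < n) return(integer(0))
  seq.int(n, hi, by = n)
}

#' Bisection self-alignment scan of one mature sequence
#'
#' Divides the sequence at each admissible site into a prefix and a suffix,
#' locally aligns the two segments, and calls the sequence `strong` if any
#' split scores above the threshold, `weak` if the best score is positive
#' but at or below it, and `none` otherwise. Ties for the best split go to
#' the smallest split position.
#'
#' @param sequence One mature amino-acid string.
#' @param config A [spa_config()].
#' @param accession Identifier carried into the result.
#' @return A one-row tibble with columns `accession`, `mature_length`,
#'   `cys_count`, `filter_status`, `call`, `best_split`, `best_score`,
#'   `n_splits_scored` and a `split_scores` list-column of per-site tibbles
#'   (`split`, `score`).
#' @export
spa_scan <- function(sequence, config = spa_config(), accession = "seq") {
  stopifnot(length(sequence) == 1L, nzchar(sequence))
  len <- nchar(sequence)
  cys <- cysteine_count(sequence)
  status <- spa_prefilter(sequence, config)
  empty_scores <- tibble::tibble(split = integer(0), score = numeric(0))
  if (status != "pass") {
    return(tibble::tibble(
      accession = accession, mature_length = len, cys_count = cys,
      filter_status = status, call = "none",
      best_split = NA_integer_, best_score = NA_real_, n_splits_scored = 0L,
      split_scores = list(empty_scores)
    ))
  }
  splits <- spa_split_points(len, config)
  if (length(splits) == 0L) {
    return(tibble::tibble(
      accession = accession, mature_length = len, cys_count = cys,
      filter_status = status, call = "none",
      best_split = NA_integer_, best_score = NA_real_, n_splits_scored = 0L,
      split_scores = list(empty_scores)
    ))
  }
  scores <- vapply(splits, function(k) {
    alignment_scores(substr(sequence, 1L, k),
                     substr(sequence, k + 1L, len),
                     scheme = config$scheme, type = "local")
  }, numeric(1))
  best_i <- which.max(scores)  # which.max takes the first maximum: smallest k
  best <- scores[best_i]
  call <- if (best > config$strong_threshold) "strong"
          else if (best > 0) "weak" else "none"
  tibble::tibble(
    accession = accession, mature_length = len, cys_count = cys,
    filter_status = status, call = call,
    best_split = splits[best_i], best_score = best,
    n_splits_scored = length(splits),
    split_scores = list(tibble::tibble(split = splits, score = scores))
  )
}

#' Run the tandem-repeat scan over a set of records
#'
#' Trims signal regions ([add_mature()]), then applies [spa_scan()] to every
#' record in input order. Per-status counts are reported via `message()`.
#'
#' @param records A records tibble (see [read_fasta()]).
#' @param signals Optional signal-annotation tibble
#'   ([read_signal_annotations()]).
#' @param config A [spa_config()].
#' @return A tibble of class `spa_result`, one row per record, shaped as in
#'   [spa_scan()].
#' @export
run_spa <- function(records, signals = NULL, config = spa_config()) {
  assert_records(records)
  records <- add_mature(records, signals)
  if (nrow(records) == 0L) {
    out <- tibble::tibble(
      accession = character(), mature_length = integer(),
      cys_count = integer(), filter_status = character(), call = character(),
      best_split = integer(), best_score = numeric(),
      n_splits_scored = integer(), split_scores = list()
    )
  } else {
    out <- dplyr::bind_rows(
      purrr::map2(records$mature, records$accession,
                  function(s, a) spa_scan(s, config, accession = a)))
  }
  counts <- table(factor(out$call, levels = c("strong", "weak", "none")))
  message("scan: ", nrow(out), " sequence(s); ",
          paste(names(counts), as.integer(counts), sep = "=", collapse = ", "))
  class(out) <- c("spa_result", class(out))
  out
}

#' Write scan results as TSV
#'
#' @param spa A [run_spa()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spa_tsv <- function(spa, path) {
  flat <- dplyr::select(tibble::as_tibble(spa), -"split_scores")
  write_screp_tsv(flat, path)
}
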