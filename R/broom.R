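#' Tidy a scan result
#'
#' Drops the per-split list-column, leaving one plain row per sequence.
#'
#' @param x A `spa_result` tibble from [run_spa()].
#' @param ... Unused.
#' @return A tibble without list-columns.
#' @exportS3Method generics::tidy
tidy.spa_result <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -"split_scores")
}

#' One-row summary of a scan result
#'
#' @param x A `spa_result` tibble from [run_spa()].
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_pass_filter`, `n_strong`, `n_weak`,
#'   `n_none`, `strong_rate`.
#' @exportS3Method generics::glance
glance.spa_result <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    n_pass_filter = sum(x$filter_status == "pass"),
    n_strong = sum(x$call == "strong"),
    n_weak = sum(x$call == "weak"),
    n_none = sum(x$call == "none"),
    strong_rate = if (nrow(x)) sum(x$call == "strong") / nrow(x) else NA_real_
  )
}

#' One-row summary of a homology screen
#'
#' @param x A `screp_hits` tibble from [homology_screen()].
#' @param ... Unused.
#' @return A one-row tibble: `n_alignments`, `n_passing`,
#'   `n_screps_with_hits`, `n_references_hit`.
#' @exportS3Method generics::glance
glance.screp_hits <- function(x, ...) {
  tibble::tibble(
    n_alignments = nrow(x),
    n_passing = sum(x$passes),
    n_screps_with_hits = dplyr::n_distinct(x$screp_id[x$passes]),
    n_references_hit = dplyr::n_distinct(x$toxin_id[x$passes])
  )
}

#' Tidy an architecture set
#'
#' @param x A `screp_architectures` tibble from [build_architectures()].
#' @param ... Unused.
#' @return The per-protein table without the `arch` list-column.
#' @exportS3Method generics::tidy
tidy.screp_architectures <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -"arch")
}
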