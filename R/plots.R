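#' Plot a cysteine-density histogram
#'
#' @param histogram A [density_histogram()] table (or a records tibble, in
#'   which case the histogram is computed first).
#' @param bin_width Bin width when `histogram` is a records tibble.
#' @return A ggplot object.
#' @export
plot_density_histogram <- function(histogram, bin_width = 1.0) {
  if (!"bin_lower_pct" %in% names(histogram)) {
    histogram <- density_histogram(histogram, bin_width)
  }
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = .data$bin_lower_pct, y = .data$count)) +
    ggplot2::geom_col(width = bin_width * 0.9, fill = "#4878a8") +
    ggplot2::labs(x = "cysteine density (%)", y = "sequences",
                  title = "Cysteine density distribution") +
    ggplot2::theme_minimal()
}

#' Plot the split-score profile of one scanned sequence
#'
#' Shows the self-alignment score at each division site, the strong-call
#' threshold, and the best split.
#'
#' @param spa A [run_spa()] result.
#' @param accession Which record to plot; defaults to the first.
#' @param strong_threshold Threshold line to draw.
#' @return A ggplot object.
#' @export
plot_split_profile <- function(spa, accession = NULL, strong_threshold = 30) {
  if (is.null(accession)) accession <- spa$accession[1]
  row <- spa[spa$accession == accession, , drop = FALSE]
  if (nrow(row) == 0) stop("no such accession: ", accession, call. = FALSE)
  scores <- row$split_scores[[1]]
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$split, y = .data$score)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = strong_threshold, linetype = "dashed",
                        colour = "#b04030") +
    ggplot2::geom_vline(xintercept = row$best_split, linetype = "dotted") +
    ggplot2::labs(x = "division site (residues from N-terminus)",
                  y = "local self-alignment score",
                  title = paste0(accession, " (", row$call, ")")) +
    ggplot2::theme_minimal()
}

#' @rdname plot_split_profile
#' @param object A `spa_result` tibble.
#' @param ... Passed to [plot_split_profile()].
#' @exportS3Method ggplot2::autoplot
autoplot.spa_result <- function(object, ...) plot_split_profile(object, ...)

#' Plot domain-type frequencies
#'
#' Bars give the number of proteins containing each domain type; the
#' overlaid points give the mean copy number per protein.
#'
#' @param report A [domain_frequency_report()] table.
#' @param top Show at most this many types.
#' @return A ggplot object.
#' @export
plot_domain_frequency <- function(report, top = 20) {
  report <- utils::head(report, top)
  report$domain_type <- stats::reorder(report$domain_type, -report$n_proteins)
  scale <- max(report$n_proteins) / max(report$mean_copies_per_protein)
  ggplot2::ggplot(report, ggplot2::aes(x = .data$domain_type)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_proteins), fill = "#4878a8") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_copies_per_protein * scale),
                        colour = "#b04030") +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "mean copies/protein")) +
    ggplot2::labs(x = NULL, y = "proteins with domain") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
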