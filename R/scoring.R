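#' Alignment scoring scheme
#'
#' Bundles the substitution matrix, affine gap penalties and Karlin-Altschul
#' statistical constants used by every alignment in the package. Defaults are
#' BLOSUM62 with BLAST's standard gapped penalties (gap open 11, gap extend 1)
#' and the published Karlin-Altschul constants for that parameter set
#' (lambda = 0.267, K = 0.041). A gap of length g costs
#' `gap_open + g * gap_extend`.
#'
#' @param matrix A symmetric integer substitution matrix with amino-acid row
#'   and column names, or the name of a matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM80"`, `"PAM250"`).
#' @param gap_open Positive penalty charged once per gap opened.
#' @param gap_extend Positive penalty charged per gap residue.
#' @param lambda Karlin-Altschul lambda for this matrix/gap combination.
#' @param k Karlin-Altschul K for this matrix/gap combination.
#' @return An object of class `scoring_scheme`.
#' @examples
#' sc <- scoring_scheme()
#' sc$matrix["C", "C"] # 9
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, k = 0.041) {
  if (is.character(matrix)) {
    name <- matrix
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    matrix <- get(name, envir = e)
  } else {
    name <- "custom"
  }
  if (!is.matrix(matrix) || is.null(rownames(matrix)) ||
      !isTRUE(all.equal(matrix, t(matrix)))) {
    stop("substitution matrix must be symmetric with residue dimnames", call. = FALSE)
  }
  if (gap_open < gap_extend || gap_extend < 1) {
    stop("require gap_open >= gap_extend >= 1", call. = FALSE)
  }
  if (lambda <= 0 || k <= 0) stop("lambda and k must be positive", call. = FALSE)
  structure(
    list(matrix = matrix, matrix_name = name,
         gap_open = gap_open, gap_extend = gap_extend,
         lambda = lambda, k = k),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> ", x$matrix_name,
      " gap ", x$gap_open, "/", x$gap_extend,
      "  lambda=", x$lambda, " K=", x$k, "\n", sep = "")
  invisible(x)
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix layout used by NCBI BLAST (`#` comments, a
#' header row of residue letters, one labelled row per residue), e.g. the
#' files distributed with BLAST+.
#'
#' @param path Path to the matrix file.
#' @return An integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  tab <- utils::read.table(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "integer"
  if (!identical(rownames(m), colnames(m))) {
    stop("matrix rows and columns disagree in ", path, call. = FALSE)
  }
  m
}
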