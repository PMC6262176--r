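# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Pick the working sequence column: prefer `mature` when present.
seq_column <- function(records) {
  if ("mature" %in% names(records)) "mature" else "sequence"
}

assert_records <- function(records, arg = "records") {
  if (!is.data.frame(records) || !all(c("accession", "sequence") %in% names(records))) {
    stop("`", arg, "` must be a data frame with at least `accession` and `sequence` columns",
         call. = FALSE)
  }
  invisible(records)
}

# All pipeline writers: UTF-8, LF, tab-separated, one '#'-prefixed header line.
write_screp_tsv <- function(x, path) {
  header <- paste0("#", paste(names(x), collapse = "\t"))
  body <- do.call(paste, c(lapply(x, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- "NA"
    col
  }), sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_screp_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  cols <- strsplit(sub("^#", "", lines[[1]]), "\t", fixed = TRUE)[[1]]
  if (length(lines) == 1L) {
    out <- stats::setNames(rep(list(character()), length(cols)), cols)
    return(tibble::as_tibble(out))
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  mat <- do.call(rbind, lapply(body, function(f) c(f, rep(NA_character_, length(cols) - length(f)))))
  out <- tibble::as_tibble(stats::setNames(as.data.frame(mat, stringsAsFactors = FALSE), cols))
  # best-effort numeric conversion
  for (nm in names(out)) {
    v <- out[[nm]]
    v[v == "NA"] <- NA
    suppressWarnings(num <- as.numeric(v))
    out[[nm]] <- if (all(is.na(num) == is.na(v))) num else v
  }
  out
}
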