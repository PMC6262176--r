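#' Read a protein FASTA file
#'
#' Reads a protein FASTA file into a tibble, one row per entry, preserving
#' input order. UniProt-style headers `sp|ACC|NAME desc` / `tr|ACC|NAME desc`
#' are parsed into `accession = ACC` with `reviewed = TRUE` for `sp` entries;
#' for plain headers the first whitespace-delimited token is the accession.
#' Sequences are uppercased and internal whitespace removed. A terminal or
#' internal `*` is stripped with a warning; any other non-amino-acid
#' character is an error reported with its line number.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `accession`, `description`, `sequence`,
#'   `reviewed` (logical, `NA` for plain headers).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path, call. = FALSE)
  headers <- names(set)
  seqs <- unname(toupper(gsub("[ \t]", "", as.character(set))))

  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("stripping '*' characters from ",
            sum(grepl("*", seqs, fixed = TRUE)), " sequence(s)", call. = FALSE)
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  bad <- !grepl(paste0("^[", paste(.aa_tolerated, collapse = ""), "]+$"), seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    lineno <- fasta_body_line(path, i, seqs[i])
    stop("non-amino-acid character in entry ", i, " (line ", lineno, ") of ",
         path, call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for entry ", which(!nzchar(seqs))[1], " in ", path,
         call. = FALSE)
  }

  up <- regmatches(headers, regexec("^(sp|tr)\\|([^| ]+)\\|(\\S*)\\s*(.*)$", headers))
  accession <- character(length(headers))
  description <- character(length(headers))
  reviewed <- rep(NA, length(headers))
  for (i in seq_along(headers)) {
    hit <- up[[i]]
    if (length(hit)) {
      accession[i] <- hit[3]
      description[i] <- trimws(paste(hit[4], hit[5]))
      reviewed[i] <- hit[2] == "sp"
    } else {
      tok <- strsplit(headers[i], "\\s+")[[1]]
      accession[i] <- tok[1]
      description[i] <- trimws(sub("^\\S+\\s*", "", headers[i]))
    }
  }
  dup <- accession[duplicated(accession)]
  if (length(dup)) {
    stop("duplicate accession in ", path, ": ", dup[1], call. = FALSE)
  }
  tibble::tibble(accession = accession, description = description,
                 sequence = seqs, reviewed = reviewed)
}

# locate the first body line of entry `i` whose text contains a character
# outside the tolerated alphabet, for error reporting
fasta_body_line <- function(path, i, seq) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^>", lines)
  from <- starts[i] + 1L
  to <- if (i < length(starts)) starts[i + 1L] - 1L else length(lines)
  pat <- paste0("[^", paste(.aa_tolerated, collapse = ""), "* \t]")
  for (j in seq(from, to)) {
    if (grepl(pat, toupper(lines[j]))) return(j)
  }
  from
}

#' Write records to FASTA
#'
#' Writes `>accession description` headers (description omitted when empty)
#' with 80-column sequence wrapping; round-trips with [read_fasta()] for
#' plain-header input.
#'
#' @param records A records tibble with `accession`, `sequence` and
#'   optionally `description` columns.
#' @param path Output path.
#' @param use_mature Write the `mature` column instead of `sequence` when
#'   present.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, use_mature = FALSE) {
  assert_records(records)
  col <- if (use_mature && "mature" %in% names(records)) "mature" else "sequence"
  set <- Biostrings::AAStringSet(records[[col]])
  desc <- if ("description" %in% names(records)) records$description else ""
  names(set) <- ifelse(is.na(desc) | desc == "", records$accession,
                       paste(records$accession, desc))
  Biostrings::writeXStringSet(set, path, width = 80)
  invisible(path)
}

#' Read signal-region annotations
#'
#' Reads a two-column tab-separated table of `accession`, `signal_end`, where
#' `signal_end` is the 1-based index of the last residue of the signal
#' region. A header line is detected (and skipped) when the second field is
#' non-numeric.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `accession` and integer `signal_end`.
#' @export
read_signal_annotations <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(accession = character(), signal_end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- fields[[1]]
  start <- 1L
  if (length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))) {
    start <- 2L  # header line
  }
  acc <- character(0)
  ends <- integer(0)
  for (i in seq(start, length.out = length(fields) - start + 1L)) {
    f <- fields[[i]]
    if (length(f) < 2) stop("line ", i, ": expected 2 tab-separated columns", call. = FALSE)
    val <- suppressWarnings(as.numeric(f[2]))
    if (is.na(val) || val != round(val) || val <= 0) {
      stop("line ", i, ": signal_end must be a positive integer, got '",
           f[2], "'", call. = FALSE)
    }
    acc <- c(acc, f[1])
    ends <- c(ends, as.integer(val))
  }
  tibble::tibble(accession = acc, signal_end = ends)
}

#' Mature (signal-trimmed) sequence
#'
#' Returns residues `signal_end + 1 .. length` (1-based inclusive) when a
#' signal end is given, else the full sequence. Trimming the whole sequence
#' away is an error.
#'
#' @param sequence Amino-acid string(s).
#' @param signal_end 1-based index of the last signal residue, or `NA` for
#'   none; recycled against `sequence`.
#' @return Character vector of mature sequences.
#' @examples
#' mature_sequence("MKLLVVAACD", 4) # "VVAACD"
#' @export
mature_sequence <- function(sequence, signal_end = NA_integer_) {
  n <- nchar(sequence)
  signal_end <- rep_len(signal_end, length(sequence))
  bad <- !is.na(signal_end) & signal_end >= n
  if (any(bad)) {
    stop("empty mature sequence: signal_end >= sequence length for entry ",
         which(bad)[1], call. = FALSE)
  }
  ifelse(is.na(signal_end), sequence, substr(sequence, signal_end + 1L, n))
}

#' Attach mature sequences to a records tibble
#'
#' Joins signal annotations onto the records and adds `mature` and
#' `mature_length` columns. Records without an annotation are treated as
#' already mature (a message reports how many).
#'
#' @param records A records tibble (see [read_fasta()]).
#' @param signals Optional tibble from [read_signal_annotations()]; when
#'   `NULL`, an existing `signal_end` column on `records` is used if present.
#' @return `records` with `signal_end`, `mature` and `mature_length` columns.
#' @export
add_mature <- function(records, signals = NULL) {
  assert_records(records)
  if (!is.null(signals)) {
    records$signal_end <- NULL
    records <- dplyr::left_join(
      records, dplyr::select(signals, "accession", "signal_end"),
      by = "accession"
    )
  }
  if (!"signal_end" %in% names(records)) records$signal_end <- NA_integer_
  n_unann <- sum(is.na(records$signal_end))
  if (n_unann > 0 && n_unann < nrow(records)) {
    message(n_unann, " record(s) lack a signal annotation; treated as already mature")
  }
  records$mature <- mature_sequence(records$sequence, records$signal_end)
  records$mature_length <- nchar(records$mature)
  records
}

#' Read InterProScan tab-separated output
#'
#' Parses the standard InterProScan TSV dialect (>= 11 tab-separated
#' columns: accession, md5, length, analysis, signature accession, signature
#' description, start, stop, score, status, date, then optional InterPro
#' accession and description). Coordinates are 1-based inclusive.
#'
#' @param path Path to an InterProScan `.tsv` file.
#' @return A tibble of domain annotations with columns `accession`,
#'   `analysis`, `signature_id`, `signature_desc`, integer `start`, `stop`,
#'   `interpro_id`, `interpro_desc` (empty strings when absent).
#' @export
read_interproscan_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- tibble::tibble(
    accession = character(), analysis = character(),
    signature_id = character(), signature_desc = character(),
    start = integer(), stop = integer(),
    interpro_id = character(), interpro_desc = character()
  )
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 11) {
      stop("row ", i, ": expected >= 11 tab-separated columns, got ",
           length(f), call. = FALSE)
    }
    start <- as.integer(f[7]); stop_ <- as.integer(f[8])
    if (is.na(start) || is.na(stop_) || start < 1 || start > stop_) {
      stop("row ", i, ": invalid coordinates start=", f[7], " stop=", f[8],
           call. = FALSE)
    }
    rows[[i]] <- tibble::tibble(
      accession = f[1], analysis = f[4],
      signature_id = f[5], signature_desc = f[6],
      start = start, stop = stop_,
      interpro_id = if (length(f) >= 12) f[12] else "",
      interpro_desc = if (length(f) >= 13) f[13] else ""
    )
  }
  out <- dplyr::bind_rows(rows)
  out$interpro_id[out$interpro_id == "-"] <- ""
  out$interpro_desc[out$interpro_desc == "-"] <- ""
  out
}
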