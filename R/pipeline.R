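#' Run the full discovery pipeline
#'
#' Runs the stages in discovery order — signal trimming, bisection scan,
#' refinement of the strong hits (annotation-driven exclusion, redundancy
#' clustering, cysteine-density histogram), architecture classification and
#' the optional reference-toxin screen — writing one tab-separated file per
#' stage plus a per-stage sequence-count summary to standard error. Only
#' strong scan calls proceed to refinement; downstream stages consume only
#' cluster representatives of kept records.
#'
#' @param fasta Path to the input protein FASTA.
#' @param out_dir Output directory (created if missing).
#' @param signals Optional path to a signal-annotation TSV.
#' @param interpro Optional path to an InterProScan TSV (enables exclusion
#'   and architectures).
#' @param reference Optional path to a reference toxin FASTA (enables the
#'   homology screen).
#' @param config A [pipeline_config()] list.
#' @param dry_run Print the resolved configuration and exit without reading
#'   or writing anything else.
#' @return Invisibly, a named list of the per-stage result tibbles and a
#'   `counts` tibble (stage, n) replicating the count-flow report.
#' @export
run_pipeline <- function(fasta, out_dir, signals = NULL, interpro = NULL,
                         reference = NULL, config = pipeline_config(),
                         dry_run = FALSE) {
  if (dry_run) {
    message("resolved configuration:")
    message(yaml::as.yaml(config_for_echo(config)))
    return(invisible(NULL))
  }
  for (p in c(fasta, signals, interpro, reference)) {
    if (!is.null(p) && !file.exists(p)) stop("missing input: ", p, call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  message("config:\n", yaml::as.yaml(config_for_echo(config)))

  scheme <- config$scheme
  spa_cfg <- spa_config(min_len = config$spa$min_len,
                        max_len = config$spa$max_len,
                        min_cys = config$spa$min_cys,
                        step_n = config$spa$step_n,
                        strong_threshold = config$spa$strong_threshold,
                        scheme = scheme)

  records <- read_fasta(fasta)
  sig <- if (!is.null(signals)) read_signal_annotations(signals) else NULL
  counts <- tibble::tibble(stage = "input", n = nrow(records))
  message("[input] ", nrow(records), " sequence(s)")

  spa <- run_spa(records, sig, spa_cfg)
  write_spa_tsv(spa, file.path(out_dir, "spa.tsv"))
  strong <- add_mature(records, sig)
  strong <- strong[spa$call == "strong", , drop = FALSE]
  counts <- dplyr::bind_rows(counts, tibble::tibble(stage = "spa_strong",
                                                    n = nrow(strong)))
  message("[spa] ", nrow(strong), " strong hit(s)")

  anns <- if (!is.null(interpro)) read_interproscan_tsv(interpro) else
    read_interproscan_tsv(tempfile_empty())
  excl <- exclude_non_screps(strong, anns,
                             exclusion_terms = config$refine$exclusion_terms,
                             exclusion_ids = config$refine$exclusion_ids)
  write_screp_tsv(
    dplyr::select(excl, "accession", "kept", "exclusion_reason"),
    file.path(out_dir, "exclusion.tsv"))
  kept <- excl[excl$kept, , drop = FALSE]
  counts <- dplyr::bind_rows(counts, tibble::tibble(stage = "refined",
                                                    n = nrow(kept)))
  message("[refine] ", nrow(kept), " kept, ", sum(!excl$kept), " removed")

  hist <- density_histogram(kept, bin_width = config$refine$density_bin_width)
  write_screp_tsv(hist, file.path(out_dir, "density_histogram.tsv"))

  clusters <- if (nrow(kept) > 0) {
    cluster_redundant(kept, identity = config$refine$cluster_identity,
                      scheme = scheme)
  } else {
    tibble::tibble(accession = character(), cluster = integer(),
                   representative = character(), is_representative = logical(),
                   identity_to_rep = numeric())
  }
  write_screp_tsv(clusters, file.path(out_dir, "clusters.tsv"))
  reps <- kept[kept$accession %in%
                 clusters$accession[clusters$is_representative], , drop = FALSE]
  counts <- dplyr::bind_rows(counts, tibble::tibble(stage = "non_redundant",
                                                    n = nrow(reps)))
  message("[cluster] ", nrow(reps), " non-redundant cluster(s)")

  archs <- NULL
  if (!is.null(interpro) && nrow(reps) > 0) {
    archs <- build_architectures(reps, anns, scheme = scheme)
    write_screp_tsv(dplyr::select(tibble::as_tibble(archs), -"arch"),
                    file.path(out_dir, "architecture.tsv"))
    write_screp_tsv(domain_frequency_report(archs),
                    file.path(out_dir, "domain_frequency.tsv"))
    message("[arch] ", sum(archs$repeat_class == "pure"), " pure, ",
            sum(archs$repeat_class == "combinatorial"), " combinatorial")
  }

  hits <- NULL
  if (!is.null(reference) && nrow(reps) > 0) {
    ref <- read_fasta(reference)
    hits <- homology_screen(reps, ref,
                            evalue_cutoff = config$homology$evalue_cutoff,
                            bit_cutoff = config$homology$bit_cutoff,
                            scheme = scheme)
    write_screp_tsv(tibble::as_tibble(hits), file.path(out_dir, "hits.tsv"))
    counts <- dplyr::bind_rows(counts, tibble::tibble(stage = "homology_hits",
                                                      n = nrow(hits)))
    message("[screen] ", nrow(hits), " passing alignment(s)")
  }

  write_screp_tsv(counts, file.path(out_dir, "counts.tsv"))
  invisible(list(spa = spa, exclusion = excl, clusters = clusters,
                 histogram = hist, architectures = archs, hits = hits,
                 counts = counts))
}

tempfile_empty <- function() {
  f <- tempfile(fileext = ".tsv")
  file.create(f)
  f
}

#' Pipeline configuration
#'
#' Materializes every stage default into one nested list; unknown keys are
#' rejected. Can be loaded from a YAML file whose top-level sections are
#' `spa`, `refine` and `homology`.
#'
#' @param path Optional YAML file; values there override the defaults.
#' @param ... Named overrides of the form `spa = list(step_n = 5)`.
#' @return A nested configuration list with a `scheme` entry.
#' @export
pipeline_config <- function(path = NULL, ...) {
  defaults <- list(
    spa = list(min_len = 20L, max_len = 500L, min_cys = 4L, step_n = 10L,
               strong_threshold = 30L),
    refine = list(density_bin_width = 1.0,
                  exclusion_terms = c("cytochrome c", "thioredoxin"),
                  exclusion_ids = character(),
                  cluster_identity = 0.99),
    homology = list(evalue_cutoff = 1e-6, bit_cutoff = 35)
  )
  user <- list(...)
  if (!is.null(path)) {
    user <- utils::modifyList(yaml::read_yaml(path), user)
  }
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) stop("unknown config section(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(bad)) stop("unknown key(s) in section '", sec, "': ",
                          paste(bad, collapse = ", "), call. = FALSE)
    defaults[[sec]] <- utils::modifyList(defaults[[sec]], user[[sec]])
  }
  defaults$scheme <- scoring_scheme()
  defaults
}

config_for_echo <- function(config) {
  config$scheme <- list(matrix = config$scheme$matrix_name,
                        gap_open = config$scheme$gap_open,
                        gap_extend = config$scheme$gap_extend,
                        lambda = config$scheme$lambda,
                        k = config$scheme$k)
  config
}

#' Summarize a pipeline output directory
#'
#' Reads the stage TSVs back and reports row counts plus the headline
#' tables; missing stage files are listed as absent rather than failing.
#'
#' @param out_dir A [run_pipeline()] output directory.
#' @return A list with `counts` (tibble: file, n_rows, present) and the
#'   parsed `histogram`, `architecture`, `domain_frequency` and `hits`
#'   tables (`NULL` when absent).
#' @export
pipeline_report <- function(out_dir) {
  files <- c(spa = "spa.tsv", exclusion = "exclusion.tsv",
             clusters = "clusters.tsv", histogram = "density_histogram.tsv",
             architecture = "architecture.tsv",
             domain_frequency = "domain_frequency.tsv", hits = "hits.tsv",
             counts = "counts.tsv")
  present <- file.exists(file.path(out_dir, files))
  tabs <- stats::setNames(vector("list", length(files)), names(files))
  for (i in seq_along(files)) {
    if (present[i]) tabs[[i]] <- read_screp_tsv(file.path(out_dir, files[i]))
  }
  n_rows <- vapply(tabs, function(t) if (is.null(t)) NA_integer_ else nrow(t),
                   integer(1))
  summary <- tibble::tibble(file = unname(files), n_rows = unname(n_rows),
                            present = unname(present))
  if (!is.null(tabs$hits) && nrow(tabs$hits) == 0) {
    message("report: zero homology hits")
  }
  c(list(counts = summary), tabs[c("histogram", "architecture",
                                   "domain_frequency", "hits")])
}
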