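# End-to-end pipeline entry points (simulate / screen / evaluate) over a
# flat key-value run configuration; these back the command-line wrapper
# shipped in inst/scripts/timscreen.R.

log_stage <- function(fmt, ...) {
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              sprintf(fmt, ...)), file = stderr())
}

#' Read a flat key-value run configuration
#'
#' Lines of the form \code{key = value}; blank lines and \code{#} comments
#' ignored. Values are parsed as numbers where possible; comma-separated
#' values become vectors. Recognised keys include the file paths
#' (\code{cloud, ms2_events, library, spectra, calibrants, blank, truth,
#' output_dir}), the screening windows (\code{mz_ppm, rt_min,
#' ccs_true_pct, ccs_interference_pct}), extraction and MS2 parameters,
#' \code{seed}, RT widening \code{factors}, and any [scenario_config()]
#' field for simulation.
#'
#' @param path Configuration file.
#' @return Named list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) io_error(sprintf("config file '%s' not found", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L)
      config_error(sprintf("cannot parse config line: '%s'", ln))
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    cfg[[key]] <- if (!any(is.na(num))) num else parts
  }
  structure(cfg, class = c("run_config", "list"))
}

run_config_windows <- function(cfg) {
  screening_windows(
    mz_ppm = cfg$mz_ppm %||% 5,
    rt_min = cfg$rt_min %||% 0.25,
    ccs_true_pct = cfg$ccs_true_pct %||% 3,
    ccs_interference_pct = cfg$ccs_interference_pct %||% 5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_scenario_config <- function(cfg) {
  fields <- names(formals(scenario_config))
  args <- cfg[intersect(names(cfg), fields)]
  do.call(scenario_config, args)
}

need_dir <- function(path) {
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    io_error(sprintf("cannot create output directory '%s'", path))
  path
}

#' Simulate a scenario and write all shipped formats
#'
#' Generates the library, a peak cloud with MS2 events and the truth
#' ledger for the configured scenario and writes them (peak-cloud TSV,
#' MS2 event TSV, library CSV, MSP spectra, truth CSV, calibrant CSV) to
#' the output directory, printing a deterministic summary.
#'
#' @param config A \code{run_config} (or path to one, or plain list).
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  scen <- run_scenario_config(cfg)
  out <- need_dir(cfg$output_dir %||% ".")
  cal <- default_calibration()
  log_stage("simulate: generating library (%d analytes)", scen$n_analytes)
  lib <- generate_library(scen, cal)
  log_stage("simulate: rendering peak cloud")
  cloud <- generate_peak_cloud(lib, scen, cal,
                               concentration = cfg$concentration %||% 100)
  truth <- attr(cloud, "truth")
  paths <- list(
    cloud = file.path(out, "peak_cloud.tsv"),
    ms2 = file.path(out, "peak_cloud_ms2.tsv"),
    library = file.path(out, "library.csv"),
    spectra = file.path(out, "spectra.msp"),
    truth = file.path(out, "truth.csv"),
    calibrants = file.path(out, "calibrants.csv"))
  write_peak_cloud(cloud, paths$cloud, paths$ms2)
  write_library_csv(lib, paths$library)
  write_msp(attr(lib, "spectra"), paths$spectra)
  write_truth_csv(truth[, !grepl("^concentration$", names(truth))], paths$truth)
  write_calibrants_csv(tunemix_calibrants(), paths$calibrants)
  cat(sprintf("simulated scenario seed=%d: %d analytes, %d truth peaks (%d interferences), %d cloud points, %d MS2 events\n",
              as.integer(scen$seed), nrow(lib), nrow(truth),
              sum(truth$role == "interference"), nrow(cloud),
              nrow(attr(cloud, "ms2_events"))))
  invisible(paths)
}

#' Run the full screening pipeline from files
#'
#' Calibrate from the calibrant table, screen the cloud against the
#' library with MS2 confidence assignment, and write the annotation
#' report CSV plus an evaluation report (JSON and text).
#'
#' @param config A \code{run_config} (or path, or plain list) with at
#'   least \code{cloud}, \code{library} and \code{calibrants} paths.
#' @return Invisibly, the annotation report.
#' @export
run_screen <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  for (key in c("cloud", "library", "calibrants"))
    if (is.null(cfg[[key]]))
      if (key == "calibrants")
        data_error("timscreen_uncalibrated", "no calibrant table configured; mobility data cannot be converted to CCS")
      else config_error(sprintf("config key '%s' is required", key))
  out <- need_dir(cfg$output_dir %||% ".")
  log_stage("screen: fitting calibration from %s", cfg$calibrants)
  cal <- fit_ccs_calibration(read_calibrants_csv(cfg$calibrants))
  log_stage("screen: calibration slope %.2f (%d calibrants, RMS %.3g)",
            cal$slope, cal$n_calibrants, cal$residual_rms)
  cloud <- read_peak_cloud(cfg$cloud, ms2_path = cfg$ms2_events,
                           polarity = cfg$polarity %||% "positive")
  lib <- read_library_csv(cfg$library)
  spectra <- if (!is.null(cfg$spectra)) read_msp(cfg$spectra) else NULL
  blank <- if (!is.null(cfg$blank)) read_peak_cloud(cfg$blank) else NULL
  windows <- run_config_windows(cfg)
  log_stage("screen: %d library ions against %d points", nrow(lib), nrow(cloud))
  ann <- screen(cloud, lib, windows, cal, spectra = spectra,
                blank_cloud = blank,
                fragment_tol = cfg$fragment_tol %||% 0.01,
                score_threshold = cfg$score_threshold %||% 0.7)
  counts <- table(factor(ann$category, annotation_categories))
  log_stage("screen: %s",
            paste(sprintf("%d %s", as.integer(counts), names(counts)), collapse = ", "))
  write_annotation_csv(ann, file.path(out, "annotations.csv"))
  rep <- evaluation_report(ann)
  write_evaluation_report(rep, file.path(out, "evaluation"))
  invisible(ann)
}

#' Run the evaluation experiments from files
#'
#' RT-window sensitivity over the configured widening factors, spectral
#' coverage, trendline fits, and (when a truth ledger is supplied) the
#' confusion matrix against ground truth.
#'
#' @inheritParams run_screen
#' @return Invisibly, the \code{evaluation_report}.
#' @export
run_evaluate <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  out <- need_dir(cfg$output_dir %||% ".")
  cal <- if (!is.null(cfg$calibrants))
    fit_ccs_calibration(read_calibrants_csv(cfg$calibrants))
  else default_calibration()
  cloud <- read_peak_cloud(cfg$cloud, ms2_path = cfg$ms2_events,
                           polarity = cfg$polarity %||% "positive")
  lib <- read_library_csv(cfg$library)
  spectra <- if (!is.null(cfg$spectra)) read_msp(cfg$spectra) else NULL
  windows <- run_config_windows(cfg)
  factors <- cfg$factors %||% c(1, 10)
  log_stage("evaluate: RT widening factors %s", paste(factors, collapse = ", "))
  sens <- rt_window_sensitivity(cloud, lib, windows, cal, factors = factors,
                                spectra = spectra)
  ann <- attr(sens, "baseline") %||%
    screen(cloud, lib, windows, cal, spectra = spectra)
  truth <- if (!is.null(cfg$truth)) read_truth_csv(cfg$truth) else NULL
  conf <- if (!is.null(truth)) confusion_matrix(ann, truth, lib, windows)
  feats <- if (!is.null(truth)) truth[, c("mz", "ccs", "charge")] else {
    ok <- !is.na(ann$measured_ccs)
    data.frame(mz = ann$mz[ok], ccs = ann$measured_ccs[ok], charge = 1L)
  }
  tl <- fit_trendlines(feats)
  rep <- evaluation_report(ann, rt_sensitivity = sens, trendlines = tl,
                           confusion = conf)
  write_evaluation_report(rep, file.path(out, "evaluation"))
  invisible(rep)
}

#' Write an evaluation report as JSON and readable text
#'
#' @param report An [evaluation_report()].
#' @param stem Output path without extension; writes \code{<stem>.json}
#'   and \code{<stem>.txt}.
#' @return Invisibly, the JSON path.
#' @export
write_evaluation_report <- function(report, stem) {
  json_path <- paste0(stem, ".json")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE, pretty = TRUE)
  txt_path <- paste0(stem, ".txt")
  con <- file(txt_path, "w")
  on.exit(close(con))
  sink(con)
  print(report)
  sink()
  invisible(json_path)
}

#' Check an evaluation-report JSON against the shipped schema
#'
#' Structural validation against \code{inst/extdata/}
#' \code{evaluation_report_schema.json}: required fields present with the
#' expected types.
#'
#' @param path Path to a report JSON.
#' @return TRUE when valid, otherwise a character vector of problems.
#' @export
validate_report_json <- function(path) {
  schema <- jsonlite::read_json(system.file("extdata",
                                            "evaluation_report_schema.json",
                                            package = "timscreen"))
  rep <- jsonlite::read_json(path)
  probs <- character()
  for (field in names(schema$required)) {
    if (!field %in% names(rep)) {
      probs <- c(probs, sprintf("missing required field '%s'", field))
      next
    }
    type <- schema$required[[field]]
    val <- rep[[field]]
    ok <- switch(type,
                 number = is.numeric(val) || is.null(val),
                 object = is.list(val) || is.null(val),
                 TRUE)
    if (!ok) probs <- c(probs, sprintf("field '%s' is not of type %s", field, type))
  }
  if (length(probs)) probs else TRUE
}
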