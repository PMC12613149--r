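# Plain-text round-tripping for the shipped formats: 4D peak-cloud TSV,
# MS2 event TSV, screening-library CSV, truth-ledger CSV and calibrant
# CSV. Numbers are written with 10 significant digits so that
# write -> read -> write is byte-identical.

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.10g", x))
fmt_chr <- function(x) ifelse(is.na(x), "NA", as.character(x))

write_table_lines <- function(cols, path, sep) {
  lines <- c(paste(names(cols), collapse = sep),
             do.call(paste, c(cols, sep = sep)))
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  if (!ok) io_error(sprintf("cannot write '%s'", path))
  invisible(path)
}

#' Write a 4D peak cloud to tab-separated text
#'
#' Columns \code{rt_min, inv_k0, mz, intensity}, one row per centroided
#' point. MS2 events go to a companion TSV (\code{precursor_mz,
#' inv_k0_low, inv_k0_high, rt_min, fragments}, fragments serialised as
#' semicolon-separated \code{mz:intensity} pairs).
#'
#' @param cloud A \code{peak_cloud}.
#' @param path Output TSV.
#' @param ms2_path Optional companion MS2 event TSV.
#' @return Invisibly, \code{path}.
#' @export
write_peak_cloud <- function(cloud, path, ms2_path = NULL) {
  write_table_lines(list(rt_min = fmt_num(cloud$rt_min),
                         inv_k0 = fmt_num(cloud$inv_k0),
                         mz = fmt_num(cloud$mz),
                         intensity = fmt_num(cloud$intensity)),
                    path, "\t")
  ev <- attr(cloud, "ms2_events")
  if (!is.null(ms2_path) && !is.null(ev)) {
    frags <- vapply(ev$fragments, function(f)
      paste(sprintf("%.10g:%.10g", f$mz, f$intensity), collapse = ";"),
      character(1))
    write_table_lines(list(precursor_mz = fmt_num(ev$precursor_mz),
                           inv_k0_low = fmt_num(ev$inv_k0_low),
                           inv_k0_high = fmt_num(ev$inv_k0_high),
                           rt_min = fmt_num(ev$rt_min),
                           fragments = frags),
                      ms2_path, "\t")
  }
  invisible(path)
}

#' Read a 4D peak cloud from tab-separated text
#'
#' @param path Peak-cloud TSV written by [write_peak_cloud()].
#' @param ms2_path Optional companion MS2 event TSV.
#' @param polarity Ionisation mode recorded in the metadata.
#' @param mobility_range Scanned 1/K0 range (metadata).
#' @param rt_range Run RT range; defaults to the data range.
#' @return A \code{peak_cloud} (sorted by m/z).
#' @export
read_peak_cloud <- function(path, ms2_path = NULL, polarity = "positive",
                            mobility_range = c(0.45, 1.45), rt_range = NULL) {
  if (!file.exists(path)) io_error(sprintf("peak cloud file '%s' not found", path))
  cloud <- utils::read.delim(path, colClasses = "numeric")
  if (!all(c("rt_min", "inv_k0", "mz", "intensity") %in% names(cloud)))
    io_error(sprintf("'%s' lacks the rt_min/inv_k0/mz/intensity header", path))
  cloud <- cloud[order(cloud$mz), , drop = FALSE]
  rownames(cloud) <- NULL
  events <- NULL
  if (!is.null(ms2_path)) {
    if (!file.exists(ms2_path)) io_error(sprintf("MS2 event file '%s' not found", ms2_path))
    ev <- utils::read.delim(ms2_path, colClasses = c(rep("numeric", 4), "character"))
    frag <- lapply(strsplit(ev$fragments, ";", fixed = TRUE), function(p) {
      m <- do.call(rbind, strsplit(p, ":", fixed = TRUE))
      data.frame(mz = as.numeric(m[, 1L]), intensity = as.numeric(m[, 2L]))
    })
    events <- data.frame(precursor_mz = ev$precursor_mz,
                         inv_k0_low = ev$inv_k0_low,
                         inv_k0_high = ev$inv_k0_high,
                         rt_min = ev$rt_min,
                         fragments = I(frag))
  }
  if (is.null(rt_range)) rt_range <- range(cloud$rt_min)
  structure(cloud, mz_sorted = TRUE, ms2_events = events,
            metadata = list(polarity = polarity, mobility_range = mobility_range,
                            rt_range = rt_range),
            class = c("peak_cloud", "data.frame"))
}

#' Write a screening library to CSV
#'
#' Header \code{compound_id,name,formula,adduct,charge,polarity,mz,rt_min,
#' ccs,additional_ccs}; additional CCS values semicolon-separated.
#'
#' @param library Screening library data.frame.
#' @param path Output CSV.
#' @return Invisibly, \code{path}.
#' @export
write_library_csv <- function(library, path) {
  write_table_lines(list(compound_id = fmt_chr(library$compound_id),
                         name = fmt_chr(library$name),
                         formula = fmt_chr(library$formula),
                         adduct = fmt_chr(library$adduct),
                         charge = fmt_num(library$charge),
                         polarity = fmt_chr(library$polarity),
                         mz = fmt_num(library$mz),
                         rt_min = fmt_num(library$rt_min),
                         ccs = fmt_num(library$ccs),
                         additional_ccs = fmt_chr(library$additional_ccs)),
                    path, ",")
}

#' Read a screening library from CSV
#'
#' @param path Library CSV (see [write_library_csv()] for the layout).
#' @return data.frame of class \code{screening_library}.
#' @export
read_library_csv <- function(path) {
  if (!file.exists(path)) io_error(sprintf("library file '%s' not found", path))
  lib <- utils::read.csv(path, colClasses = c(
    compound_id = "character", name = "character", formula = "character",
    adduct = "character", polarity = "character",
    additional_ccs = "character"))
  lib$formula[is.na(lib$formula)] <- ""
  lib$additional_ccs[is.na(lib$additional_ccs)] <- ""
  lib$charge <- as.integer(lib$charge)
  class(lib) <- c("screening_library", "data.frame")
  lib
}

#' Parse semicolon-separated additional CCS values
#'
#' @param x Character vector as stored in the library CSV.
#' @return List of numeric vectors.
#' @export
parse_additional_ccs <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(p) {
    v <- suppressWarnings(as.numeric(p))
    v[!is.na(v)]
  })
}

#' Write / read a synthetic truth ledger CSV
#'
#' @param truth The \code{SyntheticTruth} data.frame.
#' @param path CSV path.
#' @return Invisibly \code{path}; the reader returns the ledger.
#' @export
write_truth_csv <- function(truth, path) {
  cols <- lapply(names(truth), function(nm) {
    v <- truth[[nm]]
    if (is.numeric(v)) fmt_num(v) else fmt_chr(v)
  })
  names(cols) <- names(truth)
  write_table_lines(cols, path, ",")
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  if (!file.exists(path)) io_error(sprintf("truth file '%s' not found", path))
  chr <- c("peak_id", "role", "compound_id", "target_compound_id")
  tr <- utils::read.csv(path)
  for (nm in intersect(chr, names(tr))) tr[[nm]] <- as.character(tr[[nm]])
  tr
}

#' Write / read a calibrant table CSV
#'
#' Header \code{name,mz,charge,ccs,inv_k0}; units Th, e, A^2, V s/cm2.
#'
#' @param calibrants Calibrant data.frame.
#' @param path CSV path.
#' @return Invisibly \code{path}; the reader returns the table.
#' @export
write_calibrants_csv <- function(calibrants, path) {
  write_table_lines(list(name = fmt_chr(calibrants$name),
                         mz = fmt_num(calibrants$mz),
                         charge = fmt_num(calibrants$charge),
                         ccs = fmt_num(calibrants$ccs),
                         inv_k0 = fmt_num(calibrants$inv_k0)),
                    path, ",")
}

#' @rdname write_calibrants_csv
#' @export
read_calibrants_csv <- function(path) {
  if (!file.exists(path)) io_error(sprintf("calibrant file '%s' not found", path))
  cal <- utils::read.csv(path, colClasses = c(name = "character"))
  cal$charge <- as.integer(cal$charge)
  cal
}

#' Write an annotation report to CSV
#'
#' One row per library ion with all deltas, the category, MS2 score and
#' confidence level.
#'
#' @param annotations A [screen()] report.
#' @param path CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_annotation_csv <- function(annotations, path) {
  df <- as.data.frame(annotations)
  cols <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (is.numeric(v)) fmt_num(v) else fmt_chr(v)
  })
  names(cols) <- names(df)
  write_table_lines(cols, path, ",")
}
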