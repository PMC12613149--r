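# Mobility-gated MS2 spectral extraction, cosine library matching and
# identification-confidence assignment.

#' Construct an MS2 spectrum object
#'
#' @param precursor_mz Precursor m/z (Th).
#' @param fragments data.frame with columns \code{mz}, \code{intensity};
#'   stored sorted by m/z.
#' @param mobility_gate Optional 1/K0 interval the spectrum was gated on.
#' @param rt Retention time (min) or NA.
#' @param isolation_halfwidth Precursor isolation half-width (Th);
#'   default 0.5, a 1 m/z isolation window.
#' @param name Optional identifier.
#' @return list of class \code{ms2_spectrum}.
#' @export
ms2_spectrum <- function(precursor_mz, fragments, mobility_gate = NULL,
                         rt = NA_real_, isolation_halfwidth = 0.5,
                         name = NULL) {
  stopifnot_scalar_pos(precursor_mz, "precursor_mz")
  if (!is.data.frame(fragments) || !all(c("mz", "intensity") %in% names(fragments)))
    invalid_input("`fragments` must have columns mz and intensity")
  if (any(fragments$intensity < 0)) invalid_input("fragment intensities must be >= 0")
  fragments <- fragments[order(fragments$mz), c("mz", "intensity"), drop = FALSE]
  rownames(fragments) <- NULL
  structure(list(name = name, precursor_mz = precursor_mz,
                 isolation_halfwidth = isolation_halfwidth,
                 mobility_gate = mobility_gate, rt = rt,
                 fragments = fragments),
            class = "ms2_spectrum")
}

as_ms2_spectrum <- function(x) {
  if (inherits(x, "ms2_spectrum")) return(x)
  ms2_spectrum(x$precursor_mz, x$fragments, name = x$name)
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("MS2 spectrum%s: precursor m/z %.4f, %d fragments\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$precursor_mz, nrow(x$fragments)))
  if (!is.null(x$mobility_gate))
    cat(sprintf("  mobility gate %.4f-%.4f V s/cm2\n",
                x$mobility_gate[1], x$mobility_gate[2]))
  invisible(x)
}

#' Extract a mobility-gated MS2 spectrum from a peak cloud
#'
#' Merges all recorded data-dependent MS2 events whose precursor lies
#' within the isolation half-width of the requested m/z and whose mobility
#' gate overlaps the requested interval (and, optionally, whose RT lies in
#' \code{rt_window}); fragment intensities are summed across events.
#' Requesting a narrow gate around one species of a co-isolated pair
#' returns only that species' events -- the mechanism by which trapped ion
#' mobility cleans fragment spectra of coeluting contaminants.
#'
#' @param cloud A \code{peak_cloud} carrying an \code{ms2_events}
#'   attribute.
#' @param precursor_mz Requested precursor m/z (Th).
#' @param mobility_gate Length-2 1/K0 interval; use the scanned range for
#'   ungated extraction.
#' @param rt_window Optional length-2 RT interval (min).
#' @param isolation_halfwidth Precursor tolerance (Th, default 0.5).
#' @param merge_tol Fragment m/z tolerance when summing across events.
#' @return An \code{ms2_spectrum}, or NULL when no event matches.
#' @export
extract_ms2 <- function(cloud, precursor_mz, mobility_gate, rt_window = NULL,
                        isolation_halfwidth = 0.5, merge_tol = 0.005) {
  if (length(mobility_gate) != 2L || mobility_gate[1] > mobility_gate[2])
    invalid_input("`mobility_gate` must be an ordered length-2 interval")
  ev <- attr(cloud, "ms2_events")
  if (is.null(ev) || !nrow(ev)) return(NULL)
  keep <- abs(ev$precursor_mz - precursor_mz) <= isolation_halfwidth &
    ev$inv_k0_high >= mobility_gate[1] & ev$inv_k0_low <= mobility_gate[2]
  if (!is.null(rt_window))
    keep <- keep & ev$rt_min >= rt_window[1] & ev$rt_min <= rt_window[2]
  if (!any(keep)) return(NULL)
  frag <- merge_fragments(do.call(rbind, ev$fragments[keep]), tol = merge_tol)
  ms2_spectrum(precursor_mz, frag, mobility_gate = mobility_gate,
               rt = mean(ev$rt_min[keep]))
}

#' Cosine similarity between two MS2 spectra
#'
#' Fragments are paired one-to-one within \code{fragment_tol}, greedily by
#' descending intensity product on square-root-scaled intensities; the
#' score is the squared cosine numerator over the intensity norms,
#' \eqn{(\sum \sqrt{I_a I_b})^2 / (\sum I_a \sum I_b)}, in [0, 1]. The
#' score is symmetric and invariant to rescaling either spectrum.
#'
#' @param query,reference \code{ms2_spectrum} objects.
#' @param fragment_tol Fragment m/z tolerance (Th, default 0.01).
#' @return list of class \code{spectral_match}: \code{score},
#'   \code{n_matched_fragments}.
#' @export
cosine_score <- function(query, reference, fragment_tol = 0.01) {
  stopifnot_scalar_pos(fragment_tol, "fragment_tol")
  fq <- query$fragments
  fr <- reference$fragments
  empty_score <- structure(list(score = 0, n_matched_fragments = 0L),
                           class = "spectral_match")
  if (!nrow(fq) || !nrow(fr) || sum(fq$intensity) == 0 || sum(fr$intensity) == 0)
    return(empty_score)
  a <- sqrt(fq$intensity)
  b <- sqrt(fr$intensity)
  cand <- which(abs(outer(fq$mz, fr$mz, "-")) <= fragment_tol, arr.ind = TRUE)
  if (!nrow(cand)) return(empty_score)
  prod <- a[cand[, 1L]] * b[cand[, 2L]]
  ord <- order(-prod)
  used_q <- logical(nrow(fq))
  used_r <- logical(nrow(fr))
  num <- 0
  n_matched <- 0L
  for (k in ord) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (used_q[i] || used_r[j]) next
    used_q[i] <- TRUE; used_r[j] <- TRUE
    num <- num + prod[k]
    n_matched <- n_matched + 1L
  }
  structure(list(score = num^2 / (sum(a^2) * sum(b^2)),
                 n_matched_fragments = n_matched),
            class = "spectral_match")
}

#' @export
print.spectral_match <- function(x, ...) {
  cat(sprintf("spectral match: score %.4f (%d matched fragments)\n",
              x$score, x$n_matched_fragments))
  invisible(x)
}

#' Assign an identification-confidence level
#'
#' Level 1 (confirmed by MS2) when a spectral match with score at or above
#' the threshold is present; level 4 (no MS2 coverage or poor matching)
#' otherwise. Only meaningful for annotations with a matched mobilogram
#' peak.
#'
#' @param annotation One annotation record (a one-row slice of an
#'   [screen()] report, or any list with a \code{category} element).
#' @param match A [cosine_score()] result, or NULL when no spectrum was
#'   acquired.
#' @param score_threshold Minimum score (default 0.7).
#' @return Integer, 1 or 4.
#' @export
assign_confidence <- function(annotation, match, score_threshold = 0.7) {
  category <- annotation$category
  if (length(category) != 1L || !category %in% c("true_annotation", "true_with_interference"))
    ts_error("timscreen_invalid_state",
             "confidence levels apply only to annotations with a matched peak")
  if (!is.null(match) && !is.na(match$score) && match$score >= score_threshold) 1L else 4L
}

#' Write spectra to an MSP file
#'
#' @param spectra List of spectra (\code{ms2_spectrum} objects or lists
#'   with \code{name}, \code{precursor_mz}, \code{fragments}).
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
write_msp <- function(spectra, path) {
  lines <- unlist(lapply(spectra, function(s) {
    f <- s$fragments
    c(paste0("Name: ", s$name),
      sprintf("PrecursorMZ: %.10g", s$precursor_mz),
      sprintf("Num Peaks: %d", nrow(f)),
      sprintf("%.10g %.10g", f$mz, f$intensity),
      "")
  }))
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  if (!ok) io_error(sprintf("cannot write MSP file '%s'", path))
  invisible(path)
}

#' Read spectra from an MSP file
#'
#' Understands the minimal MSP dialect written by [write_msp()]: Name,
#' PrecursorMZ and Num Peaks headers followed by "mz intensity" peak
#' lines.
#'
#' @param path MSP file.
#' @return Named list of spectra, each a list with \code{name},
#'   \code{precursor_mz}, \code{fragments}.
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) io_error(sprintf("MSP file '%s' not found", path))
  lines <- readLines(path)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!grepl("^Name:", lines[i])) { i <- i + 1L; next }
    name <- sub("^Name:\\s*", "", lines[i])
    prec <- NA_real_
    npk <- 0L
    i <- i + 1L
    while (i <= n && !grepl("^Num Peaks:", lines[i])) {
      if (grepl("^PrecursorMZ:", lines[i]))
        prec <- as.numeric(sub("^PrecursorMZ:\\s*", "", lines[i]))
      i <- i + 1L
    }
    if (i <= n) {
      npk <- as.integer(sub("^Num Peaks:\\s*", "", lines[i]))
      i <- i + 1L
    }
    frag <- if (npk > 0L) {
      mat <- do.call(rbind, strsplit(trimws(lines[i:(i + npk - 1L)]), "\\s+"))
      i <- i + npk
      data.frame(mz = as.numeric(mat[, 1L]), intensity = as.numeric(mat[, 2L]))
    } else data.frame(mz = numeric(), intensity = numeric())
    spectra[[name]] <- list(name = name, precursor_mz = prec, fragments = frag)
  }
  spectra
}
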