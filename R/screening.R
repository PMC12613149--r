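# Suspect-screening annotation: m/z - RT - CCS windows, classification of
# extracted-mobilogram peaks into true annotations, interferences to true
# annotations, false-positive annotations, ambiguous and not-detected
# cases, plus library-construction rules (characteristic-peak selection
# and dimer assessment).

#' Screening annotation windows
#'
#' The windows that define a true annotation (m/z within \code{mz_ppm},
#' RT within \code{rt_min}, CCS within \code{ccs_true_pct} of the library
#' value) and the boundary beyond which a mobilogram peak is associated
#' as a distinct interfering species (\code{ccs_interference_pct}).
#' Defaults: 5 ppm, 0.25 min, 3 and 5 percent. Peaks falling between the
#' two CCS thresholds are deliberately counted toward neither side.
#'
#' @param mz_ppm m/z half-window (ppm).
#' @param rt_min RT half-window (min).
#' @param ccs_true_pct Relative CCS window for a true annotation (percent).
#' @param ccs_interference_pct Relative CCS boundary beyond which an EIM
#'   peak is a distinct interference (percent).
#' @return list of class \code{screening_windows}.
#' @export
screening_windows <- function(mz_ppm = 5, rt_min = 0.25, ccs_true_pct = 3,
                              ccs_interference_pct = 5) {
  for (nm in c("mz_ppm", "rt_min", "ccs_true_pct", "ccs_interference_pct"))
    stopifnot_scalar_pos(get(nm), nm)
  if (ccs_true_pct > ccs_interference_pct)
    invalid_input("`ccs_true_pct` must not exceed `ccs_interference_pct`")
  structure(list(mz_ppm = mz_ppm, rt_min = rt_min, ccs_true_pct = ccs_true_pct,
                 ccs_interference_pct = ccs_interference_pct),
            class = "screening_windows")
}

#' Classify the mobilogram peaks found for one library ion
#'
#' Relative CCS deviations are computed against the library reference CCS
#' (signed; thresholds act on the absolute value). The matched peak is the
#' most intense peak within the true-annotation window (ties broken by
#' smallest |deviation|); peaks beyond the interference boundary are
#' distinct interfering species; peaks between the two thresholds count
#' toward neither.
#'
#' @param peaks [detect_peaks()] output with \code{ccs} filled.
#' @param reference_ccs Library CCS (A^2).
#' @param windows A [screening_windows()].
#' @return list with \code{matched_peak} (one-row data.frame or NULL),
#'   \code{interference_peaks}, \code{band_peaks} (the in-between cases),
#'   \code{n_true_window} (how many peaks fell inside the true-annotation
#'   window; more than one flags isomers the mobility dimension cannot
#'   separate at the annotation level)
#'   and \code{category}, one of \code{true_annotation},
#'   \code{true_with_interference}, \code{false_positive},
#'   \code{ambiguous}, \code{not_detected}.
#' @export
classify_eim_peaks <- function(peaks, reference_ccs, windows = screening_windows()) {
  stopifnot_scalar_pos(reference_ccs, "reference_ccs")
  if (is.null(peaks) || nrow(peaks) == 0L)
    return(list(matched_peak = NULL,
                interference_peaks = peaks[0, ],
                band_peaks = peaks[0, ],
                n_true_window = 0L,
                category = "not_detected"))
  d_pct <- 100 * (peaks$ccs - reference_ccs) / reference_ccs
  peaks$delta_ccs_pct <- d_pct
  in_true <- abs(d_pct) < windows$ccs_true_pct
  in_intf <- abs(d_pct) > windows$ccs_interference_pct
  in_band <- !in_true & !in_intf
  matched <- NULL
  if (any(in_true)) {
    cand <- peaks[in_true, , drop = FALSE]
    best <- order(-cand$apex_intensity, abs(cand$delta_ccs_pct))[1L]
    matched <- cand[best, , drop = FALSE]
  }
  interference <- peaks[in_intf, , drop = FALSE]
  band <- peaks[in_band, , drop = FALSE]
  category <- if (!is.null(matched)) {
    if (nrow(interference)) "true_with_interference" else "true_annotation"
  } else if (nrow(interference)) {
    "false_positive"
  } else {
    "ambiguous"  # only in-between peaks were found
  }
  list(matched_peak = matched, interference_peaks = interference,
       band_peaks = band, n_true_window = sum(in_true), category = category)
}

#' Screen a peak cloud against a library
#'
#' For each library ion: extract the EIC in the m/z window, take the
#' detected chromatographic peak whose apex is nearest the expected RT
#' within the RT window (none: not detected), extract the EIM over that
#' peak's integration bounds, convert mobility peaks to CCS and classify
#' them against the reference CCS. Optionally performs mobility-gated MS2
#' library matching on matched peaks and assigns identification-confidence
#' levels, and drops ions whose blank-run abundance exceeds the sample's.
#'
#' @param cloud A \code{peak_cloud}.
#' @param library Screening library data.frame (columns \code{compound_id,
#'   mz, rt_min, ccs, charge, polarity}; see [generate_library()] /
#'   [read_library_csv()]).
#' @param windows A [screening_windows()].
#' @param cal A \code{ccs_calibration}.
#' @param spectra Optional named list of reference MS2 spectra (per
#'   compound id) for confidence assignment; defaults to the library's
#'   \code{spectra} attribute.
#' @param blank_cloud Optional blank-run cloud; ions with higher mean
#'   abundance in the blank are flagged and reported as not detected.
#' @param eic_bin_width,eim_bin_width,smooth_window,min_intensity Passed to
#'   the extraction stage.
#' @param fragment_tol MS2 fragment matching tolerance (Th).
#' @param score_threshold Minimum spectral score for a level-1 annotation.
#' @return data.frame of class \code{annotation_report}, one row per
#'   library ion: deltas (\code{delta_ppm}, \code{delta_rt},
#'   \code{delta_ccs_pct}), measured CCS, counts of interference and
#'   in-between peaks, \code{category}, \code{ms2_score},
#'   \code{confidence_level} and \code{blank_flag}. The per-ion peak lists
#'   are kept in the \code{details} attribute.
#' @export
screen <- function(cloud, library, windows = screening_windows(), cal,
                   spectra = NULL, blank_cloud = NULL,
                   eic_bin_width = 0.02, eim_bin_width = 0.002,
                   smooth_window = 3L, min_intensity = NULL,
                   fragment_tol = 0.01, score_threshold = 0.7) {
  check_calibration(cal)
  md <- attr(cloud, "metadata")
  if (!is.null(md$polarity) && "polarity" %in% names(library) &&
      !all(library$polarity == md$polarity))
    data_error("timscreen_polarity",
               sprintf("library polarity does not match cloud polarity (%s)", md$polarity))
  if (is.null(spectra)) spectra <- attr(library, "spectra")
  n <- nrow(library)
  rec <- data.frame(
    compound_id = library$compound_id,
    mz = library$mz, expected_rt = library$rt_min, reference_ccs = library$ccs,
    delta_ppm = NA_real_, delta_rt = NA_real_, measured_ccs = NA_real_,
    delta_ccs_pct = NA_real_, n_interference = 0L, n_band = 0L,
    n_true_window = 0L,
    category = "not_detected", ms2_score = NA_real_,
    confidence_level = NA_integer_, blank_flag = FALSE,
    stringsAsFactors = FALSE
  )
  details <- vector("list", n)
  names(details) <- library$compound_id
  for (i in seq_len(n)) {
    mz_i <- library$mz[i]
    if (!is.null(blank_cloud)) {
      s_idx <- mz_window_idx(cloud, mz_i, windows$mz_ppm)
      b_idx <- mz_window_idx(blank_cloud, mz_i, windows$mz_ppm)
      s_mean <- if (length(s_idx)) mean(cloud$intensity[s_idx]) else 0
      b_mean <- if (length(b_idx)) mean(blank_cloud$intensity[b_idx]) else 0
      if (b_mean > s_mean) {
        rec$blank_flag[i] <- TRUE
        next
      }
    }
    eic <- extract_eic(cloud, mz_i, windows$mz_ppm, eic_bin_width)
    cpeaks <- detect_peaks(eic, min_intensity, smooth_window)
    if (!nrow(cpeaks)) next
    drt <- cpeaks$apex - library$rt_min[i]
    ok <- abs(drt) <= windows$rt_min
    if (!any(ok)) next
    j <- which(ok)[which.min(abs(drt[ok]))]
    rec$delta_rt[i] <- drt[j]
    eim <- extract_eim(cloud, mz_i, windows$mz_ppm,
                       c(cpeaks$left[j], cpeaks$right[j]), eim_bin_width)
    mpeaks <- detect_peaks(eim, min_intensity, smooth_window)
    mpeaks <- mobility_peaks_to_ccs(mpeaks, mz_i, library$charge[i], cal)
    cls <- classify_eim_peaks(mpeaks, library$ccs[i], windows)
    rec$category[i] <- cls$category
    rec$n_interference[i] <- nrow(cls$interference_peaks)
    rec$n_band[i] <- nrow(cls$band_peaks)
    rec$n_true_window[i] <- cls$n_true_window
    # observed m/z: intensity-weighted mean over the integrated peak
    idx <- mz_window_idx(cloud, mz_i, windows$mz_ppm)
    idx <- idx[cloud$rt_min[idx] >= cpeaks$left[j] & cloud$rt_min[idx] <= cpeaks$right[j]]
    if (length(idx)) {
      obs_mz <- sum(cloud$mz[idx] * cloud$intensity[idx]) / sum(cloud$intensity[idx])
      rec$delta_ppm[i] <- (obs_mz - mz_i) / mz_i * 1e6
    }
    if (!is.null(cls$matched_peak)) {
      rec$measured_ccs[i] <- cls$matched_peak$ccs
      rec$delta_ccs_pct[i] <- cls$matched_peak$delta_ccs_pct
      ref_spec <- if (!is.null(spectra)) spectra[[library$compound_id[i]]] else NULL
      if (!is.null(ref_spec)) {
        gate <- c(cls$matched_peak$left, cls$matched_peak$right)
        q <- extract_ms2(cloud, mz_i, gate,
                         c(cpeaks$left[j], cpeaks$right[j]))
        if (!is.null(q)) {
          m <- cosine_score(q, as_ms2_spectrum(ref_spec), fragment_tol)
          rec$ms2_score[i] <- m$score
        }
        rec$confidence_level[i] <- if (!is.na(rec$ms2_score[i]) &&
                                       rec$ms2_score[i] >= score_threshold) 1L else 4L
      }
    }
    details[[i]] <- list(chromatographic_peak = cpeaks[j, , drop = FALSE],
                         eim_peaks = mpeaks, classification = cls)
  }
  structure(rec, details = details, windows = windows,
            class = c("annotation_report", "data.frame"))
}

annotation_categories <- c("true_annotation", "true_with_interference",
                           "false_positive", "ambiguous", "not_detected")

#' @export
print.annotation_report <- function(x, ...) {
  cat(sprintf("Screening annotation report: %d library ions\n", nrow(x)))
  counts <- table(factor(x$category, levels = annotation_categories))
  for (nm in names(counts))
    cat(sprintf("  %-24s %d\n", nm, counts[[nm]]))
  if (any(x$blank_flag)) cat(sprintf("  blank-filtered: %d\n", sum(x$blank_flag)))
  invisible(x)
}

#' @export
summary.annotation_report <- function(object, ...) {
  counts <- table(factor(object$category, levels = annotation_categories))
  matched <- object$category %in% c("true_annotation", "true_with_interference")
  out <- list(
    counts = counts,
    n = nrow(object),
    mean_abs_delta_ppm = mean(abs(object$delta_ppm), na.rm = TRUE),
    mean_abs_delta_rt = mean(abs(object$delta_rt), na.rm = TRUE),
    mean_abs_delta_ccs_pct = mean(abs(object$delta_ccs_pct[matched]), na.rm = TRUE),
    n_level1 = sum(object$confidence_level == 1L, na.rm = TRUE),
    n_matched = sum(matched)
  )
  class(out) <- "summary.annotation_report"
  out
}

#' @export
print.summary.annotation_report <- function(x, ...) {
  cat(sprintf("Annotations over %d library ions\n", x$n))
  for (nm in names(x$counts)) cat(sprintf("  %-24s %d\n", nm, x$counts[[nm]]))
  cat(sprintf("  mean |dm/z| %.2f ppm, mean |dRT| %.3f min, mean |dCCS| %.2f%%\n",
              x$mean_abs_delta_ppm, x$mean_abs_delta_rt, x$mean_abs_delta_ccs_pct))
  cat(sprintf("  level-1 annotations: %d of %d matched\n", x$n_level1, x$n_matched))
  invisible(x)
}

#' Select the characteristic mobilogram peak across a dilution series
#'
#' When an analyte shows several mobilogram peaks, one characteristic CCS
#' is chosen for the screening database: candidate CCS clusters are formed
#' by linking peaks across concentration levels within 1 percent relative
#' CCS; each cluster's summed area is regressed against concentration; the
#' lowest-CCS cluster whose response R-squared exceeds the threshold is
#' selected. If none qualifies the lowest-CCS cluster is returned flagged
#' unqualified. Remaining cluster CCS values are reported as additional
#' CCS values.
#'
#' @param per_level_peaks Named list (names = concentrations) of
#'   data.frames with columns \code{ccs} and \code{area}.
#' @param r2_threshold Minimum response R-squared (default 0.8).
#' @param link_pct Relative CCS tolerance for cross-level linking
#'   (percent).
#' @return list: \code{ccs}, \code{response_r2}, \code{qualified},
#'   \code{additional_ccs}, \code{clusters} (per-cluster summary).
#' @export
select_characteristic_peak <- function(per_level_peaks, r2_threshold = 0.8,
                                       link_pct = 1) {
  if (length(per_level_peaks) < 3L)
    data_error("timscreen_insufficient_levels",
               "characteristic-peak selection needs >= 3 concentration levels")
  conc <- as.numeric(names(per_level_peaks))
  if (any(is.na(conc))) invalid_input("list names must be numeric concentrations")
  all_pk <- do.call(rbind, lapply(seq_along(conc), function(j) {
    p <- per_level_peaks[[j]]
    if (is.null(p) || !nrow(p)) return(NULL)
    data.frame(conc = conc[j], ccs = p$ccs, area = p$area)
  }))
  if (is.null(all_pk) || !nrow(all_pk))
    invalid_input("no peaks supplied at any level")
  all_pk <- all_pk[order(all_pk$ccs), , drop = FALSE]
  grp <- cumsum(c(TRUE, diff(all_pk$ccs) / all_pk$ccs[-nrow(all_pk)] > link_pct / 100))
  clusters <- lapply(split(all_pk, grp), function(cl) {
    per_lvl <- tapply(cl$area, cl$conc, sum)
    x <- as.numeric(names(per_lvl))
    y <- as.numeric(per_lvl)
    r2 <- if (length(x) >= 3L && stats::sd(y) > 0) {
      suppressWarnings(summary(stats::lm(y ~ x))$r.squared)
    } else NA_real_
    data.frame(ccs = mean(cl$ccs), n_levels = length(x), response_r2 = r2)
  })
  cl_tbl <- do.call(rbind, clusters)
  cl_tbl <- cl_tbl[order(cl_tbl$ccs), , drop = FALSE]
  qual <- !is.na(cl_tbl$response_r2) & cl_tbl$response_r2 > r2_threshold
  if (any(qual)) {
    sel <- which(qual)[1L]          # lowest-CCS qualifying cluster
    qualified <- TRUE
  } else {
    sel <- 1L                        # lowest CCS, flagged unqualified
    qualified <- FALSE
  }
  list(ccs = cl_tbl$ccs[sel], response_r2 = cl_tbl$response_r2[sel],
       qualified = qualified,
       additional_ccs = cl_tbl$ccs[-sel],
       clusters = cl_tbl)
}

#' Assess concentration dependence of a second mobilogram peak
#'
#' Fits log(area) against log(concentration) for the lower-CCS (candidate
#' monomer) and higher-CCS (candidate dimer) peaks. Dimer formation during
#' ionization is concentration dependent, so a dimer artifact shows a
#' log-log slope near 2 against the monomer's near 1.
#'
#' @param per_level_areas_low,per_level_areas_high Named numeric vectors
#'   (names = concentrations) of peak areas for the low- and high-CCS
#'   peaks.
#' @return list with \code{label} (one of \code{consistent_with_dimer},
#'   \code{not_concentration_dependent}, \code{inconclusive}),
#'   \code{slope_low}, \code{slope_high}.
#' @export
assess_dimer <- function(per_level_areas_low, per_level_areas_high) {
  slope_of <- function(a) {
    if (is.null(names(a)))
      invalid_input("per-level areas must be named by their concentrations")
    conc <- as.numeric(names(a))
    if (length(a) < 3L)
      data_error("timscreen_insufficient_levels",
                 "dimer assessment needs >= 3 concentration levels")
    if (any(a <= 0) || any(is.na(conc)) || any(conc <= 0))
      invalid_input("areas and concentrations must be positive")
    unname(stats::coef(stats::lm(log(a) ~ log(conc)))[2L])
  }
  s_lo <- slope_of(per_level_areas_low)
  s_hi <- slope_of(per_level_areas_high)
  label <- if (s_hi - s_lo > 0.5 && s_hi > 1.5) {
    "consistent_with_dimer"
  } else if (abs(s_lo - 1) <= 0.25 && abs(s_hi - 1) <= 0.25) {
    "not_concentration_dependent"
  } else "inconclusive"
  list(label = label, slope_low = s_lo, slope_high = s_hi)
}

#' Plot an annotation report
#'
#' Two-panel base-graphics summary: category counts as bars and the
#' spectral-score distribution of matched annotations.
#'
#' @param x An [screen()] report.
#' @param ... Passed to \code{barplot}.
#' @export
plot.annotation_report <- function(x, ...) {
  counts <- table(factor(x$category, levels = annotation_categories))
  scores <- x$ms2_score[!is.na(x$ms2_score)]
  op <- graphics::par(mfrow = c(1, if (length(scores)) 2 else 1),
                      mar = c(8, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(counts, las = 2, ylab = "library ions",
                    main = "annotation categories", ...)
  if (length(scores)) {
    graphics::boxplot(scores, ylim = c(0, 1), ylab = "spectral match score",
                      main = "MS2 score distribution")
    graphics::abline(h = 0.7, lty = 2)
  }
  invisible(x)
}
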