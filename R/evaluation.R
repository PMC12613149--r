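# Desk-scale evaluation experiments: RT-window widening, spectral
# coverage, charge-state trendline fits, cross-sample feature alignment,
# prediction-accuracy statistics and truth-ledger confusion matrices.

#' False-positive counts under widened RT annotation windows
#'
#' Re-runs the screen with the RT half-window scaled by each factor, all
#' other windows fixed, and reports the number of false-positive
#' annotations per factor. Suspect screening with predicted retention
#' times needs such widened windows, at the cost of more false positives.
#'
#' @inheritParams screen
#' @param factors Numeric scaling factors, all >= 1 (e.g. \code{c(1, 2, 5,
#'   10)}).
#' @param ... Further arguments passed to [screen()].
#' @return data.frame with columns \code{factor}, \code{rt_window},
#'   \code{false_positives}; the factor-1 report is attached as the
#'   \code{baseline} attribute.
#' @export
rt_window_sensitivity <- function(cloud, library, windows = screening_windows(),
                                  cal, factors = c(1, 2, 5, 10), ...) {
  if (any(factors < 1)) invalid_input("all RT widening factors must be >= 1")
  baseline <- NULL
  res <- lapply(factors, function(f) {
    w <- screening_windows(windows$mz_ppm, windows$rt_min * f,
                           windows$ccs_true_pct, windows$ccs_interference_pct)
    ann <- screen(cloud, library, w, cal, ...)
    if (f == 1) baseline <<- ann
    data.frame(factor = f, rt_window = w$rt_min,
               false_positives = sum(ann$category == "false_positive"))
  })
  structure(do.call(rbind, res), baseline = baseline)
}

#' Spectral coverage and score distribution of a screened report
#'
#' Coverage is the percentage of annotations with a matched mobilogram
#' peak that reached confidence level 1 (confirmed by MS2); false
#' positives and undetected ions are excluded from the denominator. The
#' spectral-score distribution is summarised by mean, median and
#' quartiles.
#'
#' @param annotations An [screen()] report.
#' @return list: \code{coverage_pct} (NA with \code{defined = FALSE} when
#'   no annotation has a matched peak), \code{n_matched}, \code{n_level1},
#'   \code{scores}, \code{score_summary}.
#' @export
spectral_coverage <- function(annotations) {
  matched <- annotations$category %in% c("true_annotation", "true_with_interference")
  n_matched <- sum(matched)
  if (n_matched == 0L)
    return(list(coverage_pct = NA_real_, defined = FALSE, n_matched = 0L,
                n_level1 = 0L, scores = numeric(),
                score_summary = NULL))
  lvl1 <- sum(annotations$confidence_level[matched] == 1L, na.rm = TRUE)
  scores <- annotations$ms2_score[matched & !is.na(annotations$ms2_score)]
  qs <- if (length(scores)) stats::quantile(scores, c(0.25, 0.5, 0.75)) else NULL
  list(coverage_pct = 100 * lvl1 / n_matched, defined = TRUE,
       n_matched = n_matched, n_level1 = lvl1, scores = scores,
       score_summary = if (length(scores)) list(
         mean = mean(scores), median = stats::median(scores),
         q25 = unname(qs[1]), q75 = unname(qs[3])) else NULL)
}

#' Fit per-charge CCS-vs-m/z power-law trendlines
#'
#' Features of complex matrices group along charge-state trendlines in the
#' CCS-vs-m/z plane; this fits \eqn{CCS = A (m/z)^B} per charge state by
#' log-log least squares.
#'
#' @param features data.frame with columns \code{mz}, \code{ccs},
#'   \code{charge}.
#' @param min_features Minimum features per charge state (default 3);
#'   charges below it are skipped with a message.
#' @return data.frame with one row per fitted charge: \code{charge, n, A,
#'   B, r_squared}.
#' @export
fit_trendlines <- function(features, min_features = 3L) {
  if (!all(c("mz", "ccs", "charge") %in% names(features)))
    invalid_input("`features` needs columns mz, ccs, charge")
  out <- lapply(sort(unique(features$charge)), function(z) {
    f <- features[features$charge == z & features$mz > 0 & features$ccs > 0, ]
    if (nrow(f) < min_features) {
      message(sprintf("charge %d skipped: only %d feature(s)", z, nrow(f)))
      return(NULL)
    }
    fit <- stats::lm(log(ccs) ~ log(mz), data = f)
    data.frame(charge = z, n = nrow(f),
               A = exp(unname(stats::coef(fit)[1L])),
               B = unname(stats::coef(fit)[2L]),
               r_squared = suppressWarnings(summary(fit)$r.squared))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(charge = integer(), n = integer(), A = numeric(),
                      B = numeric(), r_squared = numeric()))
  do.call(rbind, out)
}

#' Align feature tables across samples
#'
#' Greedy one-to-one nearest-neighbour matching (in ascending m/z order)
#' of features shared between sample pairs, within joint m/z, RT and CCS
#' tolerances; reports symmetric pairwise shared counts.
#'
#' @param feature_tables Named list (>= 2) of data.frames with columns
#'   \code{mz}, \code{rt}, \code{ccs}.
#' @param mz_ppm,rt_tol,ccs_pct Matching tolerances (ppm, min, percent).
#' @return Symmetric matrix of shared-feature counts; diagonal holds table
#'   sizes.
#' @export
align_features <- function(feature_tables, mz_ppm = 5, rt_tol = 0.25,
                           ccs_pct = 3) {
  if (length(feature_tables) < 2L)
    invalid_input("feature alignment needs at least 2 tables")
  if (is.null(names(feature_tables)))
    names(feature_tables) <- paste0("table", seq_along(feature_tables))
  nt <- length(feature_tables)
  counts <- matrix(0L, nt, nt,
                   dimnames = list(names(feature_tables), names(feature_tables)))
  for (i in seq_len(nt)) counts[i, i] <- nrow(feature_tables[[i]])
  pair_count <- function(a, b) {
    a <- a[order(a$mz), , drop = FALSE]
    used <- logical(nrow(b))
    n <- 0L
    for (k in seq_len(nrow(a))) {
      ok <- which(!used &
                    abs(b$mz - a$mz[k]) / a$mz[k] * 1e6 <= mz_ppm &
                    abs(b$rt - a$rt[k]) <= rt_tol &
                    abs(b$ccs - a$ccs[k]) / a$ccs[k] * 100 <= ccs_pct)
      if (length(ok)) {
        d <- abs(b$mz[ok] - a$mz[k])
        used[ok[which.min(d)]] <- TRUE
        n <- n + 1L
      }
    }
    n
  }
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    n <- pair_count(feature_tables[[i]], feature_tables[[j]])
    counts[i, j] <- counts[j, i] <- n
  }
  counts
}

#' Prediction accuracy statistics
#'
#' R-squared (as the squared Pearson correlation, the convention for
#' CCS/RT prediction comparisons; the 1 - SSE/SST form is reported
#' alongside), RMSE and MAE in the units of the inputs.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return list: \code{r_squared} (squared Pearson correlation; NA with a
#'   message element when the predictor is constant), \code{r_squared_sse}
#'   (1 - SSE/SST), \code{rmse}, \code{mae}, \code{n}.
#' @export
prediction_accuracy <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    invalid_input("`observed` and `predicted` must have equal length")
  if (length(observed) < 2L)
    invalid_input("at least 2 value pairs are required")
  err <- observed - predicted
  r2 <- if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    NA_real_ else stats::cor(observed, predicted)^2
  list(r_squared = r2,
       r_squared_sse = 1 - sum(err^2) / sum((observed - mean(observed))^2),
       rmse = sqrt(mean(err^2)),
       mae = mean(abs(err)),
       n = length(observed),
       note = if (is.na(r2)) "undefined: constant input" else NULL)
}

#' Expected annotation categories from a truth ledger
#'
#' Derives, for each library ion, the category a correct screen must
#' report given the generated ground truth and the operative windows: a
#' present analyte with a captured interference is
#' \code{true_with_interference}; present without one,
#' \code{true_annotation}; absent with a captured interference,
#' \code{false_positive}; absent without, \code{not_detected}. An
#' interference is captured when its chromatographic position lies within
#' the RT window of the expected retention time.
#'
#' @param truth A \code{SyntheticTruth} ledger (attribute of a generated
#'   cloud).
#' @param library The screening library the cloud was generated from.
#' @param windows The [screening_windows()] used for screening.
#' @return Character vector of expected categories, one per library ion.
#' @export
expected_categories <- function(truth, library, windows = screening_windows()) {
  vapply(seq_len(nrow(library)), function(i) {
    id <- library$compound_id[i]
    present <- any(truth$role == "analyte" & truth$compound_id == id)
    intf <- truth[truth$role == "interference" &
                    !is.na(truth$target_compound_id) &
                    truth$target_compound_id == id, , drop = FALSE]
    captured <- nrow(intf) > 0 &&
      any(abs(intf$rt - library$rt_min[i]) <= windows$rt_min)
    if (present && captured) "true_with_interference"
    else if (present) "true_annotation"
    else if (captured) "false_positive"
    else "not_detected"
  }, character(1))
}

#' Confusion matrix of screened categories against ground truth
#'
#' @param annotations A [screen()] report.
#' @param truth,library,windows Passed to [expected_categories()].
#' @return list: \code{table} (expected x observed),
#'   \code{n_misclassified}, \code{mismatches} (data.frame of differing
#'   ions).
#' @export
confusion_matrix <- function(annotations, truth, library,
                             windows = screening_windows()) {
  expected <- expected_categories(truth, library, windows)
  observed <- annotations$category
  lev <- annotation_categories
  tab <- table(expected = factor(expected, lev), observed = factor(observed, lev))
  mis <- which(expected != observed)
  list(table = tab,
       n_misclassified = length(mis),
       mismatches = data.frame(compound_id = library$compound_id[mis],
                               expected = expected[mis],
                               observed = observed[mis]))
}

#' Assemble an evaluation report
#'
#' Bundles category counts, spectral coverage, RT-window sensitivity and
#' trendline fits for one screened scenario into a JSON-serialisable
#' report.
#'
#' @param annotations A [screen()] report.
#' @param rt_sensitivity Optional [rt_window_sensitivity()] result.
#' @param trendlines Optional [fit_trendlines()] result.
#' @param confusion Optional [confusion_matrix()] result.
#' @return list of class \code{evaluation_report}.
#' @export
evaluation_report <- function(annotations, rt_sensitivity = NULL,
                              trendlines = NULL, confusion = NULL) {
  counts <- as.list(table(factor(annotations$category, annotation_categories)))
  cov <- spectral_coverage(annotations)
  rep <- list(
    n_library_ions = nrow(annotations),
    category_counts = counts,
    spectral_coverage_pct = cov$coverage_pct,
    score_summary = cov$score_summary,
    rt_window_sensitivity = if (!is.null(rt_sensitivity))
      as.data.frame(rt_sensitivity) else NULL,
    trendlines = trendlines,
    confusion = if (!is.null(confusion)) list(
      n_misclassified = confusion$n_misclassified,
      table = as.data.frame(confusion$table)) else NULL
  )
  class(rep) <- "evaluation_report"
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation report (%d library ions)\n", x$n_library_ions))
  for (nm in names(x$category_counts))
    cat(sprintf("  %-24s %d\n", nm, x$category_counts[[nm]]))
  if (!is.null(x$spectral_coverage_pct) && !is.na(x$spectral_coverage_pct))
    cat(sprintf("  spectral coverage: %.1f%%\n", x$spectral_coverage_pct))
  if (!is.null(x$rt_window_sensitivity)) {
    cat("  RT-window widening:\n")
    with(x$rt_window_sensitivity,
         for (k in seq_along(factor))
           cat(sprintf("    x%-4g -> %d false positives\n",
                       factor[k], false_positives[k])))
  }
  if (!is.null(x$confusion))
    cat(sprintf("  misclassifications vs truth: %d\n", x$confusion$n_misclassified))
  invisible(x)
}
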