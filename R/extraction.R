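# Extracted ion chromatograms (EIC) and mobilograms (EIM) from a 4D peak
# cloud, plus one-dimensional peak detection used by the screening stage.

# indices of cloud points inside an m/z window; uses binary search when the
# cloud is sorted by m/z (generator and reader both sort and set the flag)
mz_window_idx <- function(cloud, mz, ppm) {
  lo <- mz * (1 - ppm * 1e-6)
  hi <- mz * (1 + ppm * 1e-6)
  if (isTRUE(attr(cloud, "mz_sorted"))) {
    v <- cloud$mz
    i1 <- findInterval(lo, v, left.open = TRUE) + 1L
    i2 <- findInterval(hi, v)
    if (i2 < i1) integer(0) else seq.int(i1, i2)
  } else {
    which(cloud$mz >= lo & cloud$mz <= hi)
  }
}

bin_trace <- function(pos, intensity, lo, hi, bin_width) {
  nbin <- max(1L, ceiling((hi - lo) / bin_width))
  grid <- lo + (seq_len(nbin) - 0.5) * bin_width
  out <- numeric(nbin)
  if (length(pos)) {
    b <- pmin(pmax(floor((pos - lo) / bin_width) + 1L, 1L), nbin)
    sums <- rowsum(intensity, b)
    out[as.integer(rownames(sums))] <- sums[, 1L]
  }
  list(grid = grid, intensity = out)
}

#' Extract an ion chromatogram
#'
#' Sums the intensity of all cloud points whose m/z lies within \code{ppm}
#' of \code{mz} into uniform RT bins spanning the run. An empty window
#' yields an all-zero trace, not an error.
#'
#' @param cloud A \code{peak_cloud} (data.frame with \code{rt_min, inv_k0,
#'   mz, intensity}).
#' @param mz Target m/z (Th).
#' @param ppm Half-width of the m/z window in ppm (default 5, the
#'   annotation window).
#' @param bin_width RT bin width in minutes (default 0.02).
#' @return Object of class \code{c("eic", "ion_trace")}: list with
#'   \code{target_mz, ppm_window, grid} (bin centres, min),
#'   \code{intensity, bin_width, axis}.
#' @export
extract_eic <- function(cloud, mz, ppm = 5, bin_width = 0.02) {
  stopifnot_scalar_pos(ppm, "ppm")
  stopifnot_scalar_pos(bin_width, "bin_width")
  stopifnot_scalar_pos(mz, "mz")
  md <- attr(cloud, "metadata")
  rtr <- if (!is.null(md$rt_range)) md$rt_range else range(cloud$rt_min)
  idx <- mz_window_idx(cloud, mz, ppm)
  bt <- bin_trace(cloud$rt_min[idx], cloud$intensity[idx], rtr[1], rtr[2], bin_width)
  structure(list(target_mz = mz, ppm_window = ppm, grid = bt$grid,
                 intensity = bt$intensity, bin_width = bin_width,
                 axis = "rt_min"),
            class = c("eic", "ion_trace"))
}

#' Extract an ion mobilogram
#'
#' Sums the intensity of all cloud points inside both the m/z window and
#' the RT bounds into uniform 1/K0 bins spanning the scanned mobility
#' range.
#'
#' @inheritParams extract_eic
#' @param rt_bounds Length-2 RT interval (min), typically the bounds of an
#'   integrated chromatographic peak.
#' @param bin_width Mobility bin width in V s/cm2 (default 0.002, about
#'   500 bins over a 0.45-1.45 scan range).
#' @return Object of class \code{c("eim", "ion_trace")} with the same
#'   fields as [extract_eic()] plus \code{rt_bounds}; \code{grid} is in
#'   V s/cm2.
#' @export
extract_eim <- function(cloud, mz, ppm = 5, rt_bounds, bin_width = 0.002) {
  stopifnot_scalar_pos(ppm, "ppm")
  stopifnot_scalar_pos(bin_width, "bin_width")
  if (length(rt_bounds) != 2L || rt_bounds[1] > rt_bounds[2])
    invalid_input("`rt_bounds` must be an ordered length-2 interval")
  md <- attr(cloud, "metadata")
  mob <- if (!is.null(md$mobility_range)) md$mobility_range else range(cloud$inv_k0)
  idx <- mz_window_idx(cloud, mz, ppm)
  idx <- idx[cloud$rt_min[idx] >= rt_bounds[1] & cloud$rt_min[idx] <= rt_bounds[2]]
  bt <- bin_trace(cloud$inv_k0[idx], cloud$intensity[idx], mob[1], mob[2], bin_width)
  structure(list(target_mz = mz, ppm_window = ppm, grid = bt$grid,
                 intensity = bt$intensity, bin_width = bin_width,
                 axis = "inv_k0", rt_bounds = rt_bounds),
            class = c("eim", "ion_trace"))
}

#' @export
print.ion_trace <- function(x, ...) {
  cat(sprintf("%s for m/z %.4f (+/- %g ppm): %d bins, max intensity %.4g\n",
              if (inherits(x, "eic")) "EIC" else "EIM",
              x$target_mz, x$ppm_window, length(x$grid), max(x$intensity)))
  invisible(x)
}

#' @export
plot.ion_trace <- function(x, ...) {
  xlab <- if (x$axis == "rt_min") "retention time (min)" else "1/K0 (V s/cm2)"
  graphics::plot(x$grid, x$intensity, type = "l", xlab = xlab,
                 ylab = "intensity", ...)
  invisible(x)
}

# centered moving average with edge shrinkage
smooth_ma <- function(y, w) {
  if (w <= 1L) return(y)
  n <- length(y)
  cs <- cumsum(c(0, y))
  h <- w %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect peaks in a one-dimensional trace
#'
#' Moving-average smoothing, local-maximum picking above an intensity
#' floor, apex refinement by three-point quadratic interpolation, bounds at
#' the first local minimum or the crossing below 10 percent of the apex
#' (valleys are shared between adjacent peaks), and trapezoidal area over
#' the bounded region of the raw trace.
#'
#' @param trace An [extract_eic()] or [extract_eim()] result.
#' @param min_intensity Detection floor applied to the smoothed trace.
#'   Default: 5 times the baseline level, estimated as the median of the
#'   nonzero bins below 10 percent of the trace maximum; when every
#'   nonzero bin exceeds that (a single clean peak), 5 percent of the
#'   maximum.
#' @param smooth_window Moving-average width in bins (default 3).
#' @return data.frame with one row per peak, sorted by apex position:
#'   \code{apex} (min or V s/cm2), \code{apex_intensity} (raw counts),
#'   \code{area}, \code{left}, \code{right} bounds and \code{ccs}
#'   (NA until [mobility_peaks_to_ccs()]). Empty traces yield zero rows.
#' @export
detect_peaks <- function(trace, min_intensity = NULL, smooth_window = 3L) {
  if (!inherits(trace, "ion_trace")) invalid_input("`trace` must be an ion_trace")
  y <- trace$intensity
  g <- trace$grid
  empty <- data.frame(apex = numeric(), apex_intensity = numeric(),
                      area = numeric(), left = numeric(), right = numeric(),
                      ccs = numeric())
  nz <- y[y > 0]
  if (!length(nz)) return(empty)
  if (is.null(min_intensity)) {
    base <- nz[nz < 0.01 * max(y)]
    min_intensity <- if (length(base)) 5 * stats::median(base) else 0.05 * max(y)
  }
  s <- smooth_ma(y, smooth_window)
  n <- length(s)
  if (n < 3L) return(empty)
  left_nb <- c(-Inf, s[-n])
  right_nb <- c(s[-1], -Inf)
  apex_idx <- which(s >= left_nb & s > right_nb & s >= min_intensity)
  # a genuine peak has signal in adjacent raw bins; an isolated single-bin
  # spike (a stray noise point) does not
  apex_idx <- apex_idx[vapply(apex_idx, function(i)
    sum(y[max(1L, i - 1L):min(n, i + 1L)] > 0) >= 2L, logical(1))]
  if (!length(apex_idx)) return(empty)
  bounds <- function(i, dir) {
    thr <- 0.1 * s[i]
    j <- i
    repeat {
      k <- j + dir
      if (k < 1L || k > n) return(j)
      if (s[k] > s[j]) return(j)     # valley: trace starts rising again
      j <- k
      if (s[j] <= thr) return(j)     # dropped below 10% of apex
    }
  }
  res <- lapply(apex_idx, function(i) {
    l <- bounds(i, -1L)
    r <- bounds(i, +1L)
    # refined apex via parabola through the smoothed triplet
    apex <- g[i]
    if (i > 1L && i < n) {
      denom <- s[i - 1L] - 2 * s[i] + s[i + 1L]
      if (denom < 0) {
        d <- 0.5 * (s[i - 1L] - s[i + 1L]) / denom
        apex <- g[i] + d * trace$bin_width
      }
    }
    seg <- l:r
    area <- if (length(seg) > 1L)
      sum(diff(g[seg]) * (y[seg][-1] + y[seg][-length(seg)]) / 2)
    else y[i] * trace$bin_width
    data.frame(apex = apex, apex_intensity = y[i], area = area,
               left = g[l], right = g[r], ccs = NA_real_)
  })
  out <- do.call(rbind, res)
  out <- out[out$area > 0, , drop = FALSE]
  out[order(out$apex), , drop = FALSE]
}

#' Attach CCS values to mobility peaks
#'
#' Converts the apex 1/K0 of each detected mobilogram peak to CCS through
#' the calibration; ordering by 1/K0 is preserved as ordering by CCS.
#'
#' @param peaks A [detect_peaks()] result from an EIM.
#' @param mz Ion m/z (Th).
#' @param charge Charge state.
#' @param cal A \code{ccs_calibration}.
#' @return \code{peaks} with the \code{ccs} column filled (A^2).
#' @export
mobility_peaks_to_ccs <- function(peaks, mz, charge, cal) {
  check_calibration(cal)
  if (nrow(peaks)) peaks$ccs <- inv_k0_to_ccs(peaks$apex, mz, charge, cal)
  peaks
}
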