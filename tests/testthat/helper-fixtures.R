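# Shared fixture builders: everything is generated in code at test time.

CAL <- default_calibration()

# small default scenario for fast unit tests
tiny_config <- function(seed = 1, ...) {
  args <- list(...)
  if (is.null(args$n_analytes)) args$n_analytes <- 10L
  if (is.null(args$n_matrix_features)) args$n_matrix_features <- 10L
  do.call(scenario_config, c(list(seed = seed), args))
}

# wrap hand-built centroid points as a peak_cloud
as_cloud <- function(df, rt_range = c(0, 10), mobility_range = c(0.45, 1.45),
                     polarity = "positive", ms2_events = NULL) {
  df <- df[order(df$mz), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, mz_sorted = TRUE, ms2_events = ms2_events,
            metadata = list(polarity = polarity, mobility_range = mobility_range,
                            rt_range = rt_range),
            class = c("peak_cloud", "data.frame"))
}

# points of a 2D Gaussian peak on regular half-offset scan grids
gauss_points <- function(rt0, k0, mz0, area, rt_sigma = 0.05, k_sigma = 0.004,
                         rt_range = c(0, 10), mobility_range = c(0.45, 1.45),
                         dt = 0.01, dk = 5e-4) {
  ri <- seq(ceiling((rt0 - 4 * rt_sigma - rt_range[1]) / dt - 0.5),
            floor((rt0 + 4 * rt_sigma - rt_range[1]) / dt - 0.5))
  ki <- seq(ceiling((k0 - 4 * k_sigma - mobility_range[1]) / dk - 0.5),
            floor((k0 + 4 * k_sigma - mobility_range[1]) / dk - 0.5))
  rt <- rt_range[1] + (ri + 0.5) * dt
  k <- mobility_range[1] + (ki + 0.5) * dk
  w <- outer(dnorm(rt, rt0, rt_sigma) * dt, dnorm(k, k0, k_sigma) * dk)
  data.frame(rt_min = rep(rt, times = length(k)),
             inv_k0 = rep(k, each = length(rt)),
             mz = mz0,
             intensity = area * as.vector(w))
}

# hand-built mobility peak table for classify_eim_peaks
fake_peaks <- function(ccs, intensity = rep(100, length(ccs))) {
  data.frame(apex = ccs / 200, apex_intensity = intensity, area = intensity,
             left = ccs / 200 - 0.01, right = ccs / 200 + 0.01, ccs = ccs)
}

# brute-force EIC oracle: plain filter-and-sum over the raw points
brute_window_sum <- function(cloud, mz, ppm, rt_bounds = NULL) {
  keep <- abs(cloud$mz - mz) / mz * 1e6 <= ppm
  if (!is.null(rt_bounds))
    keep <- keep & cloud$rt_min >= rt_bounds[1] & cloud$rt_min <= rt_bounds[2]
  sum(cloud$intensity[keep])
}

# exhaustive-pairing oracle for cosine similarity: maximises the score over
# every valid one-to-one fragment pairing within tolerance
cosine_oracle <- function(query, reference, fragment_tol = 0.01) {
  fq <- query$fragments
  fr <- reference$fragments
  if (!nrow(fq) || !nrow(fr)) return(0)
  a <- sqrt(fq$intensity)
  b <- sqrt(fr$intensity)
  best <- 0
  recurse <- function(i, used_r, num) {
    if (i > nrow(fq)) { best <<- max(best, num); return(invisible()) }
    recurse(i + 1L, used_r, num)  # leave fragment i unmatched
    for (j in seq_len(nrow(fr))) {
      if (!used_r[j] && abs(fq$mz[i] - fr$mz[j]) <= fragment_tol) {
        used_r[j] <- TRUE
        recurse(i + 1L, used_r, num + a[i] * b[j])
        used_r[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(nrow(fr)), 0)
  best^2 / (sum(a^2) * sum(b^2))
}
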