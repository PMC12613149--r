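# Synthetic 4D data generator: libraries, peak clouds, dilution series and
# a ground-truth ledger, emulating the structure of suspect-screening
# LC-TIMS-HRMS measurements of complex matrices.

#' Canonical calibration used by the synthetic generator
#'
#' A single-field CCS calibration fitted on the tune-mix calibrant table
#' with its default (noise-free) mobility values, so the slope equals the
#' generator's canonical Mason-Schamp constant.
#' @param slope Proportionality constant to emulate.
#' @return A \code{ccs_calibration}.
#' @export
default_calibration <- function(slope = 1059.9) {
  fit_ccs_calibration(tunemix_calibrants(slope = slope))
}

# deterministic sub-seed from a base seed and a string tag (kept < 2^31)
str_seed <- function(seed, tag) {
  u <- utf8ToInt(tag)
  h <- sum(u * (seq_along(u) %% 7L + 1L) * 131) %% 1000003L
  as.integer((abs(as.integer(seed)) %% 1000003L) * 2053L + h) %% 2147483629L
}

# reproducible synthetic fragment spectrum for a compound/peak tag
synth_spectrum <- function(seed, tag, precursor_mz, n_range = c(3L, 12L)) {
  set.seed(str_seed(seed, tag))
  n <- sample(seq.int(n_range[1], n_range[2]), 1L)
  top <- max(precursor_mz - 10, 55)
  mz <- sort(round(stats::runif(n, 50, top), 4))
  int <- round(stats::runif(n, 5, 100), 2)
  int <- int / max(int) * 100
  data.frame(mz = mz, intensity = int)
}

truncnorm1 <- function(n, sd, clamp) pmin(pmax(stats::rnorm(n, 0, sd), -clamp), clamp)

#' Generate a synthetic screening library
#'
#' Draws \code{n_analytes} singly charged compounds with m/z uniform in the
#' configured window, CCS on the charge-1 power-law trendline
#' \eqn{CCS = A (m/z)^B (1+\epsilon)} with Gaussian relative scatter, RT
#' uniform over the run, and a reproducible synthetic MS2 spectrum per
#' compound (attached as the \code{"spectra"} attribute, and writable to
#' MSP). CCS draws are rejected until the implied mobility lies inside the
#' scanned range.
#'
#' @param config A [scenario_config()].
#' @param cal Calibration used to check mobility-range feasibility.
#' @return data.frame of class \code{screening_library} with columns
#'   \code{compound_id, name, formula, adduct, charge, polarity, mz,
#'   rt_min, ccs, additional_ccs}; attribute \code{spectra} holds the MS2
#'   spectra keyed by compound id.
#' @export
generate_library <- function(config, cal = default_calibration()) {
  validate_scenario_config(config)
  n <- as.integer(config$n_analytes)
  if (n < 1L) config_error("n_analytes must be >= 1 to generate a library")
  set.seed(as.integer(config$seed))
  margin <- 4 * config$rt_peak_sigma
  mzr <- config$analyte_mz_range
  mob <- config$mobility_range
  mz <- stats::runif(n, mzr[1], mzr[2])
  ccs <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      eps <- stats::rnorm(1, 0, config$trendline_scatter)
      cand <- config$trendline_A[1] * mz[i]^config$trendline_B[1] * (1 + eps)
      k <- ccs_to_inv_k0(cand, mz[i], 1L, cal)
      if (k > mob[1] + 0.01 && k < mob[2] - 0.01) { ccs[i] <- cand; break }
    }
  }
  rt <- stats::runif(n, config$rt_range[1] + margin, config$rt_range[2] - margin)
  id <- sprintf("CMP%04d", seq_len(n))
  adduct <- if (config$polarity == "positive") "[M+H]+" else "[M-H]-"
  lib <- data.frame(
    compound_id = id,
    name = paste0("compound_", seq_len(n)),
    formula = "",
    adduct = adduct,
    charge = 1L,
    polarity = config$polarity,
    mz = mz,
    rt_min = rt,
    ccs = ccs,
    additional_ccs = "",
    stringsAsFactors = FALSE
  )
  spectra <- lapply(seq_len(n), function(i)
    list(name = id[i], precursor_mz = lib$mz[i],
         fragments = synth_spectrum(config$seed, id[i], lib$mz[i],
                                    config$ms2_n_fragments)))
  names(spectra) <- id
  attr(lib, "spectra") <- spectra
  class(lib) <- c("screening_library", "data.frame")
  lib
}

# Draw the ground-truth peak placement (deterministic given config seed).
# Returns the truth ledger; concentrations/areas are filled in at render
# time. Matrix features are rejection-sampled outside the joint m/z+RT
# annotation window of every library entry so the ledger alone determines
# the expected screening outcome.
draw_truth <- function(library, config, cal) {
  set.seed(str_seed(config$seed, "truth"))
  mob <- config$mobility_range
  n <- nrow(library)
  present <- stats::runif(n) >= config$missing_fraction
  rf <- stats::rlnorm(n, 0, config$response_sd)

  rows <- list()
  # analytes
  ccs_j <- truncnorm1(n, config$analyte_ccs_jitter_sd, config$analyte_ccs_jitter_max)
  rt_j <- truncnorm1(n, config$analyte_rt_jitter_sd, config$analyte_rt_jitter_max)
  mz_j <- stats::runif(n, -1, 1) * 1e-6 * library$mz  # < 1 ppm systematic error
  for (i in which(present)) {
    ccs_i <- library$ccs[i] * (1 + ccs_j[i])
    k <- ccs_to_inv_k0(ccs_i, library$mz[i], library$charge[i], cal)
    if (k <= mob[1] || k >= mob[2]) next
    rows[[length(rows) + 1L]] <- list(
      role = "analyte", compound_id = library$compound_id[i],
      target_compound_id = NA_character_, charge = library$charge[i],
      mz = library$mz[i] + mz_j[i], rt = library$rt_min[i] + rt_j[i],
      ccs = ccs_i, inv_k0 = k, rel_response = rf[i])
  }
  # interferences: m/z and CCS placed relative to the library values they
  # target; RT relative to the actual (jittered) analyte peak when the
  # analyte is present, so interferences co-elute inside its
  # chromatographic peak, and to the expected library RT when it is not
  hit <- stats::runif(n) < config$interference_fraction
  for (i in which(hit)) {
    rt_base <- if (present[i]) library$rt_min[i] + rt_j[i] else library$rt_min[i]
    ppm <- stats::runif(1, config$interference_mz_ppm_range[1],
                        config$interference_mz_ppm_range[2]) * sample(c(-1, 1), 1)
    drt <- stats::runif(1, config$interference_rt_offset_range[1],
                        config$interference_rt_offset_range[2]) * sample(c(-1, 1), 1)
    # keep the interference inside the run; try the mirrored offset first
    rt_lo <- config$rt_range[1] + 4 * config$rt_peak_sigma
    rt_hi <- config$rt_range[2] - 4 * config$rt_peak_sigma
    if (rt_base + drt < rt_lo || rt_base + drt > rt_hi) drt <- -drt
    if (rt_base + drt < rt_lo || rt_base + drt > rt_hi) next
    sgn <- sample(c(-1, 1), 1)
    k <- NA_real_
    for (try in 1:100) {
      off <- stats::runif(1, config$interference_ccs_offset_range[1],
                          config$interference_ccs_offset_range[2])
      ccs_i <- library$ccs[i] * (1 + sgn * off)
      if (ccs_i <= 0) { sgn <- -sgn; next }
      k <- ccs_to_inv_k0(ccs_i, library$mz[i], library$charge[i], cal)
      if (k > mob[1] + 0.005 && k < mob[2] - 0.005) break
      sgn <- -sgn
      k <- NA_real_
    }
    if (is.na(k)) next
    rows[[length(rows) + 1L]] <- list(
      role = "interference", compound_id = NA_character_,
      target_compound_id = library$compound_id[i], charge = library$charge[i],
      mz = library$mz[i] * (1 + ppm * 1e-6), rt = rt_base + drt,
      ccs = ccs_i, inv_k0 = k,
      rel_response = stats::rlnorm(1, 0, config$response_sd) * stats::runif(1, 0.5, 2))
  }
  # dimer artifacts: same m/z as the analyte, higher CCS, quadratic response
  if (config$dimer_fraction > 0) {
    dim_sel <- which(present & stats::runif(n) < config$dimer_fraction)
    for (i in dim_sel) {
      ccs_i <- library$ccs[i] * (1 + config$dimer_ccs_offset)
      k <- ccs_to_inv_k0(ccs_i, library$mz[i], library$charge[i], cal)
      if (k <= mob[1] || k >= mob[2]) next
      rows[[length(rows) + 1L]] <- list(
        role = "dimer_artifact", compound_id = library$compound_id[i],
        target_compound_id = library$compound_id[i], charge = library$charge[i],
        mz = library$mz[i] + mz_j[i], rt = library$rt_min[i] + rt_j[i],
        ccs = ccs_i, inv_k0 = k,
        rel_response = rf[i] / max(config$dilution_levels))
    }
  }
  # matrix features on per-charge trendlines, outside all annotation windows
  if (config$n_matrix_features > 0) {
    margin <- 4 * config$rt_peak_sigma
    zs <- sample(1:3, config$n_matrix_features, replace = TRUE,
                 prob = config$charge_state_fractions)
    for (j in seq_len(config$n_matrix_features)) {
      z <- zs[j]
      mzr <- config$matrix_mz_ranges[[z]]
      for (try in 1:200) {
        mz_f <- stats::runif(1, mzr[1], mzr[2])
        rt_f <- stats::runif(1, config$rt_range[1] + margin, config$rt_range[2] - margin)
        clash <- abs(mz_f - library$mz) / library$mz < 10e-6 &
          abs(rt_f - library$rt_min) < 0.4
        if (any(clash)) next
        eps <- stats::rnorm(1, 0, config$trendline_scatter)
        ccs_f <- config$trendline_A[z] * mz_f^config$trendline_B[z] * (1 + eps)
        k <- ccs_to_inv_k0(ccs_f, mz_f, z, cal)
        if (k <= mob[1] + 0.005 || k >= mob[2] - 0.005) next
        rows[[length(rows) + 1L]] <- list(
          role = "matrix_feature", compound_id = sprintf("MTX%04d", j),
          target_compound_id = NA_character_, charge = z,
          mz = mz_f, rt = rt_f, ccs = ccs_f, inv_k0 = k,
          rel_response = stats::rlnorm(1, 0, config$response_sd) * stats::runif(1, 0.2, 1.5))
        break
      }
    }
  }
  truth <- data.frame(
    peak_id = sprintf("PK%05d", seq_along(rows)),
    role = vapply(rows, `[[`, "", "role"),
    compound_id = vapply(rows, `[[`, "", "compound_id"),
    target_compound_id = vapply(rows, `[[`, "", "target_compound_id"),
    charge = vapply(rows, function(r) as.integer(r$charge), integer(1)),
    mz = vapply(rows, `[[`, 0, "mz"),
    rt = vapply(rows, `[[`, 0, "rt"),
    ccs = vapply(rows, `[[`, 0, "ccs"),
    inv_k0 = vapply(rows, `[[`, 0, "inv_k0"),
    rel_response = vapply(rows, `[[`, 0, "rel_response"),
    stringsAsFactors = FALSE)
  truth
}

# Sample centroided points for one Gaussian peak (RT x mobility) on the
# global scan grids, with per-point m/z jitter and multiplicative
# intensity jitter. Point weights are Riemann weights of the 2D Gaussian
# over the scan grid, so their sum approximates the ledger area to well
# under 1%.
render_peak <- function(rt0, k0, mz0, area, rt_sigma, k_sigma, config) {
  dt <- config$rt_scan_dt
  dk <- config$mobility_scan_dk
  r_orig <- config$rt_range[1]
  k_orig <- config$mobility_range[1]
  # scan centres sit at half-step offsets so they never coincide with the
  # edges of extraction bins whose width is a multiple of the scan spacing
  ri <- seq(ceiling((rt0 - 3.5 * rt_sigma - r_orig) / dt - 0.5),
            floor((rt0 + 3.5 * rt_sigma - r_orig) / dt - 0.5))
  ki <- seq(ceiling((k0 - 3.5 * k_sigma - k_orig) / dk - 0.5),
            floor((k0 + 3.5 * k_sigma - k_orig) / dk - 0.5))
  rt_pos <- r_orig + (ri + 0.5) * dt
  k_pos <- k_orig + (ki + 0.5) * dk
  wr <- stats::dnorm(rt_pos, rt0, rt_sigma) * dt
  wk <- stats::dnorm(k_pos, k0, k_sigma) * dk
  w <- as.vector(outer(wr, wk))
  np <- length(w)
  jit <- if (config$intensity_jitter > 0)
    pmax(stats::rnorm(np, 1, config$intensity_jitter), 0.01) else 1
  list(
    rt_min = rep(rt_pos, times = length(k_pos)),
    inv_k0 = rep(k_pos, each = length(rt_pos)),
    mz = mz0 * (1 + stats::runif(np, -config$mz_jitter_ppm,
                                 config$mz_jitter_ppm) * 1e-6),
    intensity = area * w * jit
  )
}

#' Generate a synthetic 4D peak cloud with ground truth
#'
#' Renders every ledger peak as a 3D Gaussian (RT profile with the
#' configured sigma; mobility profile with FWHM = 1/K0 divided by the
#' resolving power; per-point m/z jitter), adds uniform background noise,
#' and records mobility-gated data-dependent MS2 events for eligible
#' precursors, contaminated at the configured rate. The truth draw depends
#' only on the config seed, so clouds rendered at different concentrations
#' or noise seeds share identical truth structure.
#'
#' @param library A [generate_library()] result (or compatible data.frame
#'   with a \code{spectra} attribute).
#' @param config A [scenario_config()].
#' @param cal Calibration used to place peaks in mobility space.
#' @param concentration Analyte concentration (ng/mL); analyte areas are
#'   \code{rel_response * base_response * concentration}.
#' @param noise_seed Seed for rendering noise (defaults to the config
#'   seed); varying it changes point-level noise but not the truth.
#' @return A data.frame of class \code{peak_cloud} with columns
#'   \code{rt_min, inv_k0, mz, intensity}; attributes \code{truth}
#'   (the \code{SyntheticTruth} ledger, with per-cloud \code{area}),
#'   \code{ms2_events}, \code{metadata} (polarity, mobility range,
#'   concentration) and \code{calibration}.
#' @export
generate_peak_cloud <- function(library, config, cal = default_calibration(),
                                concentration = 100, noise_seed = NULL) {
  validate_scenario_config(config)
  truth <- draw_truth(library, config, cal)
  render_cloud(truth, library, config, cal, concentration,
               if (is.null(noise_seed)) config$seed else noise_seed)
}

peak_area <- function(truth, config, concentration) {
  a <- truth$rel_response * config$base_response * concentration
  q <- truth$role == "dimer_artifact"
  a[q] <- truth$rel_response[q] * config$base_response * concentration^2
  m <- truth$role == "matrix_feature"
  a[m] <- truth$rel_response[m] * config$base_response * 100  # matrix load fixed
  a
}

render_cloud <- function(truth, library, config, cal, concentration, noise_seed) {
  set.seed(str_seed(noise_seed, paste0("render", concentration)))
  truth$area <- peak_area(truth, config, concentration)
  truth$concentration <- concentration
  k_sigma <- (truth$inv_k0 / config$mobility_resolving_power) / (2 * sqrt(2 * log(2)))
  pts <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth)))
    pts[[i]] <- render_peak(truth$rt[i], truth$inv_k0[i], truth$mz[i],
                            truth$area[i], config$rt_peak_sigma, k_sigma[i],
                            config)
  # uniform background noise, snapped to the scan grids
  mob <- config$mobility_range
  mzspan <- range(c(config$analyte_mz_range, unlist(config$matrix_mz_ranges)))
  vol <- diff(config$rt_range) * diff(mob) * diff(mzspan)
  n_noise <- round(config$noise_density * vol)
  if (n_noise > 0) {
    snap <- function(x, orig, step) orig + (floor((x - orig) / step) + 0.5) * step
    pts[[length(pts) + 1L]] <- list(
      rt_min = snap(stats::runif(n_noise, config$rt_range[1], config$rt_range[2]),
                    config$rt_range[1], config$rt_scan_dt),
      inv_k0 = snap(stats::runif(n_noise, mob[1], mob[2]),
                    mob[1], config$mobility_scan_dk),
      mz = stats::runif(n_noise, mzspan[1], mzspan[2]),
      intensity = stats::rexp(n_noise, 1 / config$noise_intensity_mean)
    )
  }
  cloud <- data.frame(
    rt_min = unlist(lapply(pts, `[[`, "rt_min"), use.names = FALSE),
    inv_k0 = unlist(lapply(pts, `[[`, "inv_k0"), use.names = FALSE),
    mz = unlist(lapply(pts, `[[`, "mz"), use.names = FALSE),
    intensity = unlist(lapply(pts, `[[`, "intensity"), use.names = FALSE))
  cloud <- cloud[cloud$intensity > 0, , drop = FALSE]
  cloud <- cloud[cloud$inv_k0 > mob[1] & cloud$inv_k0 < mob[2] &
                   cloud$rt_min > config$rt_range[1] &
                   cloud$rt_min < config$rt_range[2], , drop = FALSE]
  cloud <- cloud[order(cloud$mz), , drop = FALSE]
  rownames(cloud) <- NULL
  events <- render_ms2_events(truth, library, config, k_sigma)
  structure(cloud,
            mz_sorted = TRUE,
            truth = truth,
            ms2_events = events,
            metadata = list(polarity = config$polarity,
                            mobility_range = mob,
                            concentration = concentration,
                            rt_range = config$rt_range),
            calibration = cal,
            class = c("peak_cloud", "data.frame"))
}

# Data-dependent mobility-gated MS2 events for precursor peaks. Each event
# carries the precursor's own fragments; with probability
# ms2_contamination_rate it also carries fragments of a co-isolated species
# (a ledger neighbour inside the isolation window whose mobility profile
# overlaps the gate, else an unresolved isobaric background compound).
render_ms2_events <- function(truth, library, config, k_sigma) {
  spectra <- attr(library, "spectra")
  eligible <- seq_len(nrow(truth))
  ev <- list()
  for (i in eligible) {
    if (stats::runif(1) > config$ms2_event_probability) next
    tag <- paste0("spec_", truth$peak_id[i])
    frag <- switch(truth$role[i],
      analyte = ,
      dimer_artifact = spectra[[truth$compound_id[i]]]$fragments,
      synth_spectrum(config$seed, tag, truth$mz[i], config$ms2_n_fragments))
    gw <- config$ms2_gate_halfwidth * 2 * sqrt(2 * log(2)) * k_sigma[i]
    frag$intensity <- frag$intensity * truth$area[i] / 100
    contaminated <- stats::runif(1) < config$ms2_contamination_rate
    if (contaminated) {
      nb <- which(abs(truth$mz - truth$mz[i]) <= config$isolation_halfwidth &
                    abs(truth$rt - truth$rt[i]) <= 4 * config$rt_peak_sigma &
                    abs(truth$inv_k0 - truth$inv_k0[i]) <= gw + 3 * k_sigma &
                    seq_len(nrow(truth)) != i)
      cf <- if (length(nb)) {
        j <- nb[1L]
        jf <- if (truth$role[j] %in% c("analyte", "dimer_artifact"))
          spectra[[truth$compound_id[j]]]$fragments
        else synth_spectrum(config$seed, paste0("spec_", truth$peak_id[j]),
                            truth$mz[j], config$ms2_n_fragments)
        transform(jf, intensity = intensity * truth$area[j] / 100)
      } else {
        bg <- synth_spectrum(config$seed, paste0("bgcontam_", truth$peak_id[i]),
                             truth$mz[i], config$ms2_n_fragments)
        transform(bg, intensity = intensity * truth$area[i] / 100 *
                    config$ms2_contamination_intensity)
      }
      frag <- merge_fragments(rbind(frag, cf), tol = 0.005)
    }
    frag <- frag[order(frag$mz), , drop = FALSE]
    ev[[length(ev) + 1L]] <- data.frame(
      precursor_mz = truth$mz[i],
      inv_k0_low = truth$inv_k0[i] - gw,
      inv_k0_high = truth$inv_k0[i] + gw,
      rt_min = truth$rt[i],
      fragments = I(list(frag)),
      peak_id = truth$peak_id[i],
      contaminated = contaminated,
      stringsAsFactors = FALSE)
  }
  if (!length(ev))
    return(data.frame(precursor_mz = numeric(), inv_k0_low = numeric(),
                      inv_k0_high = numeric(), rt_min = numeric(),
                      fragments = I(list()), peak_id = character(),
                      contaminated = logical()))
  do.call(rbind, ev)
}

# sum intensities of fragments closer than `tol` in m/z
merge_fragments <- function(frag, tol = 0.005) {
  frag <- frag[order(frag$mz), , drop = FALSE]
  if (nrow(frag) < 2L) return(frag)
  grp <- cumsum(c(TRUE, diff(frag$mz) > tol))
  data.frame(mz = tapply(frag$mz, grp, function(x) x[1L]),
             intensity = as.numeric(tapply(frag$intensity, grp, sum)))
}

#' Generate a dilution series of peak clouds
#'
#' One cloud per configured concentration, all sharing the identical truth
#' structure (placement, identities); analyte areas scale linearly with
#' concentration while dimer-artifact areas scale quadratically, emulating
#' concentration-dependent dimerization during ionization.
#'
#' @inheritParams generate_peak_cloud
#' @param levels Concentrations (ng/mL); defaults to
#'   \code{config$dilution_levels}.
#' @return list with \code{clouds} (named by concentration) and
#'   \code{truth}, the shared ledger with one \code{area_<level>} column
#'   per concentration.
#' @export
generate_dilution_series <- function(library, config, cal = default_calibration(),
                                     levels = NULL) {
  validate_scenario_config(config)
  if (is.null(levels)) levels <- config$dilution_levels
  if (length(levels) < 2L)
    data_error("timscreen_insufficient_levels",
               "a dilution series needs at least 2 concentration levels")
  truth <- draw_truth(library, config, cal)
  clouds <- lapply(seq_along(levels), function(j)
    render_cloud(truth, library, config, cal, levels[j],
                 noise_seed = str_seed(config$seed, paste0("level", j))))
  names(clouds) <- as.character(levels)
  for (lv in levels)
    truth[[paste0("area_", lv)]] <- peak_area(truth, config, lv)
  list(clouds = clouds, truth = truth)
}

#' @export
print.peak_cloud <- function(x, ...) {
  md <- attr(x, "metadata")
  tr <- attr(x, "truth")
  cat(sprintf("4D peak cloud: %d centroided points (%s mode)\n", nrow(x), md$polarity))
  cat(sprintf("  RT %g-%g min, 1/K0 %g-%g V s/cm2\n",
              md$rt_range[1], md$rt_range[2],
              md$mobility_range[1], md$mobility_range[2]))
  if (!is.null(tr))
    cat(sprintf("  truth: %s\n",
                paste(sprintf("%d %s", as.integer(table(tr$role)),
                              names(table(tr$role))), collapse = ", ")))
  ev <- attr(x, "ms2_events")
  if (!is.null(ev)) cat(sprintf("  MS2 events: %d\n", nrow(ev)))
  invisible(x)
}
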