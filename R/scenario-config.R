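# Scenario configuration for the synthetic 4D data generator.

#' Build a synthetic-screening scenario configuration
#'
#' Defines the statistical structure of a simulated LC-TIMS-HRMS run:
#' library size, per-charge CCS-vs-m/z trendlines, chromatographic and
#' mobility peak widths, matrix interference placement, dilution series,
#' background noise and MS2 acquisition behaviour. Defaults emulate a
#' reversed-phase screening run on a TIMS instrument scanning
#' 0.45-1.45 V s/cm2 at resolving power 200, with singly charged analytes
#' and matrix features on three charge-state trendlines; see the package
#' vignette for the rationale behind each default.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_analytes Number of library analytes.
#' @param n_matrix_features Number of background matrix features.
#' @param polarity "positive" or "negative".
#' @param charge_state_fractions Proportions of matrix features with charge
#'   1, 2, 3; must sum to 1.
#' @param trendline_A,trendline_B Per-charge power-law coefficients for
#'   CCS = A * (m/z)^B (length 3).
#' @param trendline_scatter Relative s.d. of multiplicative scatter about
#'   the trendline.
#' @param analyte_mz_range m/z window for analytes (Th).
#' @param matrix_mz_ranges List of per-charge m/z windows for matrix
#'   features.
#' @param rt_range Run RT range (min).
#' @param rt_peak_sigma Chromatographic Gaussian sigma (min).
#' @param rt_scan_dt Spacing of the global RT scan grid (min); centroided
#'   points fall on this grid, emulating a fixed acquisition cycle time.
#' @param mobility_range Scanned 1/K0 range (V s/cm2).
#' @param mobility_scan_dk Spacing of the global mobility scan grid
#'   (V s/cm2).
#' @param mobility_resolving_power Mobility resolving power (peak position
#'   over FWHM); instruments of this type reach 200-400.
#' @param analyte_ccs_jitter_sd,analyte_ccs_jitter_max Relative run-to-run
#'   CCS reproducibility of true analytes (s.d. and truncation).
#' @param analyte_rt_jitter_sd,analyte_rt_jitter_max RT reproducibility
#'   (min).
#' @param mz_jitter_ppm Per-point centroid m/z jitter (half-width, ppm).
#' @param interference_fraction Proportion of analytes receiving a matrix
#'   interference peak.
#' @param interference_ccs_offset_range Relative |CCS offset| range of
#'   interferences; the lower bound must exceed 0.05 so interferences are
#'   distinct peaks beyond the 5 percent association boundary.
#' @param interference_mz_ppm_range |m/z offset| range (ppm).
#' @param interference_rt_offset_range |RT offset| range (min).
#' @param missing_fraction Proportion of library analytes absent from the
#'   sample (their interferences, if any, become false-positive bait).
#' @param dilution_levels Concentrations (ng/mL) for dilution series.
#' @param dimer_fraction Proportion of present analytes with a
#'   concentration-dependent dimer artifact peak (same m/z, higher CCS,
#'   area growing quadratically with concentration).
#' @param dimer_ccs_offset Relative CCS offset of dimer artifacts.
#' @param noise_density Background noise points per unit
#'   (RT min) x (1/K0) x (Th) volume.
#' @param noise_intensity_mean Mean of exponential noise intensities.
#' @param intensity_jitter Relative s.d. of multiplicative per-point
#'   intensity jitter.
#' @param base_response Area counts per ng/mL for a unit response factor.
#' @param response_sd s.d. of per-compound log-normal response factors.
#' @param ms2_event_probability Probability that an eligible precursor peak
#'   yields a data-dependent MS2 event.
#' @param ms2_contamination_rate Probability that an MS2 event carries
#'   fragments of a co-isolated species (a real neighbour inside the 1 m/z
#'   isolation window and overlapping mobility gate when one exists,
#'   otherwise an unresolved isobaric background species).
#' @param ms2_contamination_intensity Intensity of contaminating fragments
#'   relative to the precursor's own.
#' @param ms2_n_fragments Range of fragment counts per synthetic spectrum.
#' @param ms2_gate_halfwidth Mobility gate half-width in units of the
#'   mobility peak FWHM.
#' @param isolation_halfwidth MS2 precursor isolation half-width (Th); the
#'   1 m/z isolation window of PASEF acquisition.
#' @return A validated list of class \code{scenario_config}.
#' @export
scenario_config <- function(seed = 1L,
                            n_analytes = 100L,
                            n_matrix_features = 200L,
                            polarity = "positive",
                            charge_state_fractions = c(0.7, 0.2, 0.1),
                            trendline_A = c(24.0, 10.7, 22.1),
                            trendline_B = c(0.34, 0.56, 0.50),
                            trendline_scatter = 0.04,
                            analyte_mz_range = c(100, 950),
                            matrix_mz_ranges = list(c(100, 950), c(400, 1000), c(500, 1000)),
                            rt_range = c(0.5, 20),
                            rt_peak_sigma = 0.05,
                            rt_scan_dt = 0.01,
                            mobility_range = c(0.45, 1.45),
                            mobility_scan_dk = 5e-4,
                            mobility_resolving_power = 200,
                            analyte_ccs_jitter_sd = 0.003,
                            analyte_ccs_jitter_max = 0.01,
                            analyte_rt_jitter_sd = 0.03,
                            analyte_rt_jitter_max = 0.1,
                            mz_jitter_ppm = 1.5,
                            interference_fraction = 0.2,
                            interference_ccs_offset_range = c(0.06, 0.35),
                            interference_mz_ppm_range = c(0, 2.5),
                            interference_rt_offset_range = c(0, 0.08),
                            missing_fraction = 0.1,
                            dilution_levels = c(0.5, 1, 5, 10, 500),
                            dimer_fraction = 0,
                            dimer_ccs_offset = 0.15,
                            noise_density = 0.1,
                            noise_intensity_mean = 20,
                            intensity_jitter = 0.05,
                            base_response = 1e4,
                            response_sd = 0.3,
                            ms2_event_probability = 0.9,
                            ms2_contamination_rate = 0.2,
                            ms2_contamination_intensity = 1.5,
                            ms2_n_fragments = c(3L, 12L),
                            ms2_gate_halfwidth = 1.5,
                            isolation_halfwidth = 0.5) {
  cfg <- structure(as.list(environment()), class = "scenario_config")
  validate_scenario_config(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Collects every violated invariant and raises a single
#' config-validation error listing all of them.
#'
#' @param config A \code{scenario_config} (or compatible list).
#' @return Invisibly TRUE when valid.
#' @export
validate_scenario_config <- function(config) {
  v <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) v <<- c(v, msg)
  rng_ok <- function(r) is.numeric(r) && length(r) == 2L && all(is.finite(r)) && r[1] <= r[2]
  chk(is.numeric(config$seed) && length(config$seed) == 1L, "seed must be a single number")
  chk(config$n_analytes >= 0, "n_analytes must be >= 0")
  chk(config$n_matrix_features >= 0, "n_matrix_features must be >= 0")
  chk(config$polarity %in% c("positive", "negative"), "polarity must be 'positive' or 'negative'")
  f <- config$charge_state_fractions
  chk(length(f) == 3L && all(f >= 0 & f <= 1) && abs(sum(f) - 1) < 1e-8,
      "charge_state_fractions must be 3 proportions summing to 1")
  chk(length(config$trendline_A) == 3L && all(config$trendline_A > 0), "trendline_A must be 3 positive values")
  chk(length(config$trendline_B) == 3L && all(config$trendline_B > 0), "trendline_B must be 3 positive values")
  chk(config$trendline_scatter >= 0, "trendline_scatter must be >= 0")
  chk(rng_ok(config$analyte_mz_range) && config$analyte_mz_range[1] > 0, "analyte_mz_range must be an ordered positive range")
  chk(rng_ok(config$rt_range), "rt_range must be ordered")
  chk(config$rt_peak_sigma > 0, "rt_peak_sigma must be > 0")
  chk(config$rt_scan_dt > 0, "rt_scan_dt must be > 0")
  chk(config$mobility_scan_dk > 0, "mobility_scan_dk must be > 0")
  chk(rng_ok(config$mobility_range) && config$mobility_range[1] > 0, "mobility_range must be an ordered positive range")
  chk(config$mobility_resolving_power > 0, "mobility_resolving_power must be > 0")
  chk(config$interference_fraction >= 0 && config$interference_fraction <= 1,
      "interference_fraction must be in [0, 1]")
  chk(rng_ok(config$interference_ccs_offset_range) && config$interference_ccs_offset_range[1] > 0.05,
      "interference_ccs_offset_range lower bound must exceed 0.05 (the 5% association boundary)")
  chk(rng_ok(config$interference_mz_ppm_range) && config$interference_mz_ppm_range[1] >= 0,
      "interference_mz_ppm_range must be an ordered non-negative range")
  chk(rng_ok(config$interference_rt_offset_range) && config$interference_rt_offset_range[1] >= 0,
      "interference_rt_offset_range must be an ordered non-negative range")
  chk(config$missing_fraction >= 0 && config$missing_fraction <= 1, "missing_fraction must be in [0, 1]")
  chk(all(config$dilution_levels > 0), "dilution_levels must be positive")
  chk(config$dimer_fraction >= 0 && config$dimer_fraction <= 1, "dimer_fraction must be in [0, 1]")
  chk(config$noise_density >= 0, "noise_density must be >= 0")
  chk(config$ms2_event_probability >= 0 && config$ms2_event_probability <= 1,
      "ms2_event_probability must be in [0, 1]")
  chk(config$ms2_contamination_rate >= 0 && config$ms2_contamination_rate <= 1,
      "ms2_contamination_rate must be in [0, 1]")
  chk(length(config$ms2_n_fragments) == 2L && config$ms2_n_fragments[1] >= 1 &&
        config$ms2_n_fragments[1] <= config$ms2_n_fragments[2],
      "ms2_n_fragments must be an ordered range of counts >= 1")
  chk(config$isolation_halfwidth > 0, "isolation_halfwidth must be > 0")
  if (length(v))
    config_error(paste0("invalid scenario configuration:\n", paste("  -", v, collapse = "\n")))
  invisible(TRUE)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Synthetic screening scenario\n")
  cat(sprintf("  seed %d | %d analytes (%s), %d matrix features\n",
              as.integer(x$seed), as.integer(x$n_analytes), x$polarity,
              as.integer(x$n_matrix_features)))
  cat(sprintf("  RT %g-%g min, mobility %g-%g V s/cm2, resolving power %g\n",
              x$rt_range[1], x$rt_range[2], x$mobility_range[1],
              x$mobility_range[2], x$mobility_resolving_power))
  cat(sprintf("  interferences: %.0f%% of analytes, |dCCS| in [%g, %g]%%\n",
              100 * x$interference_fraction,
              100 * x$interference_ccs_offset_range[1],
              100 * x$interference_ccs_offset_range[2]))
  invisible(x)
}
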