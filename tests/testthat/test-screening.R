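test_that("EIM peak classification follows the two-threshold rule", {
  w <- screening_windows()
  # a single peak at the reference CCS of simazine is a clean true annotation
  r <- classify_eim_peaks(fake_peaks(142.98), 142.98, w)
  expect_equal(r$category, "true_annotation")
  expect_equal(r$matched_peak$ccs, 142.98)
  expect_equal(nrow(r$interference_peaks), 0L)
  # matching peak plus a 14 percent offset peak: interference to a true hit
  r <- classify_eim_peaks(fake_peaks(c(100, 114)), 100, w)
  expect_equal(r$category, "true_with_interference")
  expect_equal(nrow(r$interference_peaks), 1L)
  expect_equal(r$interference_peaks$ccs, 114)
  # only a 29 percent offset peak: false positive annotation
  r <- classify_eim_peaks(fake_peaks(129), 100, w)
  expect_equal(r$category, "false_positive")
  expect_null(r$matched_peak)
  # a peak in the deliberate 3-5 percent gap is ambiguous
  r <- classify_eim_peaks(fake_peaks(104), 100, w)
  expect_equal(r$category, "ambiguous")
  expect_equal(nrow(r$band_peaks), 1L)
  # no peaks at all
  r <- classify_eim_peaks(fake_peaks(numeric(0)), 100, w)
  expect_equal(r$category, "not_detected")
})

test_that("the match is the most intense in-window peak, ties by deviation", {
  w <- screening_windows()
  r <- classify_eim_peaks(fake_peaks(c(99, 101), intensity = c(50, 200)), 100, w)
  expect_equal(r$matched_peak$ccs, 101)
  expect_equal(r$n_true_window, 2L)
  r <- classify_eim_peaks(fake_peaks(c(98, 100.5), intensity = c(100, 100)), 100, w)
  expect_equal(r$matched_peak$ccs, 100.5)
})

test_that("classification is total and exclusive over random peak sets", {
  w <- screening_windows()
  set.seed(41)
  for (rep in 1:200) {
    n <- sample(0:5, 1)
    r <- classify_eim_peaks(fake_peaks(runif(n, 80, 160)), 100, w)
    expect_length(r$category, 1L)
    expect_true(r$category %in% c("true_annotation", "true_with_interference",
                                  "false_positive", "ambiguous", "not_detected"))
    n_match <- if (is.null(r$matched_peak)) 0L else 1L
    expect_equal(n_match * 0 + nrow(r$interference_peaks) + nrow(r$band_peaks) +
                   r$n_true_window, n)
  }
})

test_that("shrinking the true window never turns false positives into hits", {
  strict <- screening_windows(ccs_true_pct = 1)
  loose <- screening_windows(ccs_true_pct = 3)
  set.seed(43)
  for (rep in 1:200) {
    pk <- fake_peaks(runif(sample(1:4, 1), 80, 160))
    c_loose <- classify_eim_peaks(pk, 100, loose)$category
    c_strict <- classify_eim_peaks(pk, 100, strict)$category
    if (c_loose == "false_positive")
      expect_true(c_strict %in% c("false_positive", "ambiguous", "not_detected"))
    expect_false(c_loose == "false_positive" && c_strict == "true_annotation")
  }
})

test_that("screening a clean analyte yields a true annotation with small deltas", {
  cfg <- tiny_config(seed = 51, n_analytes = 5, n_matrix_features = 0,
                     interference_fraction = 0, missing_fraction = 0)
  lib <- generate_library(cfg)
  cloud <- generate_peak_cloud(lib, cfg)
  ann <- screen(cloud, lib, screening_windows(), CAL)
  expect_true(all(ann$category == "true_annotation"))
  expect_true(all(abs(ann$delta_ppm) < 5))
  expect_true(all(abs(ann$delta_rt) <= 0.25))
  expect_true(all(abs(ann$delta_ccs_pct) < 3))
  expect_s3_class(ann, "annotation_report")
})

test_that("the printed interference archetypes classify as in the field", {
  # analyte present plus a 14 percent interference (the DEET-metabolite case)
  cfg14 <- tiny_config(seed = 53, n_analytes = 4, n_matrix_features = 0,
                       interference_fraction = 1, missing_fraction = 0,
                       interference_ccs_offset_range = c(0.14, 0.14))
  lib <- generate_library(cfg14)
  ann <- screen(generate_peak_cloud(lib, cfg14), lib, screening_windows(), CAL)
  expect_true(all(ann$category == "true_with_interference"))
  # analyte absent, only a 29 percent interference (the MeIQx case)
  cfg29 <- tiny_config(seed = 53, n_analytes = 4, n_matrix_features = 0,
                       interference_fraction = 1, missing_fraction = 1,
                       interference_ccs_offset_range = c(0.29, 0.29))
  lib29 <- generate_library(cfg29)
  ann29 <- screen(generate_peak_cloud(lib29, cfg29), lib29, screening_windows(), CAL)
  expect_true(all(ann29$category == "false_positive"))
})

test_that("screening reproduces the truth ledger exactly across seeds", {
  for (s in 101:105) {
    cfg <- scenario_config(seed = s, n_analytes = 50, n_matrix_features = 50)
    lib <- generate_library(cfg)
    cloud <- generate_peak_cloud(lib, cfg)
    ann <- screen(cloud, lib, screening_windows(), CAL, spectra = NULL)
    cm <- confusion_matrix(ann, attr(cloud, "truth"), lib)
    expect_equal(cm$n_misclassified, 0L)
  }
})

test_that("near-isomers inside each other's CCS window are non-separable", {
  # simazine vs desethyl-tebuthylazine: 142.98 vs 144.23 A^2 at the same RT
  expect_lt(abs(144.23 - 142.98) / 142.98 * 100, 3)
  expect_lt(abs(142.98 - 144.23) / 144.23 * 100, 3)
  mz0 <- 202.0854
  lib <- data.frame(compound_id = c("simazine", "desethyl_tebuthylazine"),
                    name = c("simazine", "desethyl-tebuthylazine"),
                    charge = 1L, polarity = "positive", mz = mz0,
                    rt_min = 11.98, ccs = c(142.98, 144.23))
  ka <- ccs_to_inv_k0(142.98, mz0, 1L, CAL)
  kb <- ccs_to_inv_k0(144.23, mz0, 1L, CAL)
  cloud <- as_cloud(rbind(
    gauss_points(11.98, ka, mz0, 1e5, k_sigma = ka / 200 / 2.3548,
                 rt_range = c(0, 20)),
    gauss_points(11.98, kb, mz0, 9e4, k_sigma = kb / 200 / 2.3548,
                 rt_range = c(0, 20))),
    rt_range = c(0, 20))
  ann <- screen(cloud, lib, screening_windows(), CAL)
  # both ions match, neither sees an interference or band peak: the pair is
  # indistinguishable at the annotation level (a single 3%-window cluster)
  expect_true(all(ann$category == "true_annotation"))
  expect_true(all(ann$n_interference == 0L))
  expect_true(all(ann$n_band == 0L))
  expect_true(all(ann$n_true_window == ann$n_true_window[1]))
})

test_that("blank-dominated ions are filtered out before annotation", {
  cfg <- tiny_config(seed = 57, n_analytes = 4, n_matrix_features = 0,
                     interference_fraction = 0, missing_fraction = 0)
  lib <- generate_library(cfg)
  cloud <- generate_peak_cloud(lib, cfg, concentration = 10)
  blank <- generate_peak_cloud(lib, cfg, concentration = 1000, noise_seed = 5)
  ann <- screen(cloud, lib, screening_windows(), CAL, blank_cloud = blank)
  expect_true(all(ann$blank_flag))
  expect_true(all(ann$category == "not_detected"))
  # a clean blank filters nothing
  empty_blank <- as_cloud(data.frame(rt_min = 1, inv_k0 = 1, mz = 50,
                                     intensity = 1))
  ann2 <- screen(cloud, lib, screening_windows(), CAL, blank_cloud = empty_blank)
  expect_false(any(ann2$blank_flag))
})

test_that("polarity mismatches abort the screen", {
  cfg <- tiny_config(seed = 59, n_analytes = 3, polarity = "negative")
  lib <- generate_library(cfg)
  cloud <- generate_peak_cloud(lib, cfg)
  lib$polarity <- "positive"
  expect_error(screen(cloud, lib, screening_windows(), CAL),
               class = "timscreen_polarity")
})

test_that("characteristic-peak selection follows the lowest-CCS + response rule", {
  conc <- c(0.5, 1, 5, 10, 500)
  # single perfectly linear cluster
  one <- lapply(conc, function(cc) data.frame(ccs = 150 + rnorm(1, 0, 0.2),
                                              area = 1000 * cc))
  names(one) <- conc
  sel <- select_characteristic_peak(one)
  expect_true(sel$qualified)
  expect_equal(sel$response_r2, 1, tolerance = 1e-9)
  expect_length(sel$additional_ccs, 0)

  # two clusters with engineered response R^2 (residual injection oracle)
  make_r2 <- function(x, r2) {
    y0 <- 50 + 12 * x
    e <- resid(lm(rnorm(length(x)) ~ x))      # orthogonal to [1, x]
    ssr <- sum((y0 - mean(y0))^2)
    y <- y0 + e * sqrt(ssr * (1 - r2) / r2 / sum(e^2))
    stopifnot(abs(suppressWarnings(summary(lm(y ~ x))$r.squared) - r2) < 1e-9)
    y
  }
  set.seed(61)
  lo_area <- make_r2(conc, 0.5)    # lower CCS, poor response
  hi_area <- make_r2(conc, 0.99)   # higher CCS, clean response
  two <- lapply(seq_along(conc), function(j)
    data.frame(ccs = c(120, 155), area = c(lo_area[j], hi_area[j])))
  names(two) <- conc
  sel2 <- select_characteristic_peak(two, r2_threshold = 0.8)
  expect_true(sel2$qualified)
  expect_equal(sel2$ccs, 155)
  expect_equal(sel2$additional_ccs, 120)
  # nothing qualifies: lowest CCS returned, flagged
  two_bad <- lapply(seq_along(conc), function(j)
    data.frame(ccs = c(120, 155), area = c(lo_area[j], lo_area[j] + 5)))
  names(two_bad) <- conc
  sel3 <- select_characteristic_peak(two_bad, r2_threshold = 0.999)
  expect_false(sel3$qualified)
  expect_equal(sel3$ccs, 120)
  expect_error(select_characteristic_peak(one[1:2]),
               class = "timscreen_insufficient_levels")
})

test_that("dimer assessment separates quadratic from linear responses", {
  conc <- c(0.5, 1, 5, 10, 500)
  lin <- 100 * conc
  quad <- 2 * conc^2
  names(lin) <- names(quad) <- conc
  r <- assess_dimer(lin, quad)
  expect_equal(r$label, "consistent_with_dimer")
  expect_equal(r$slope_low, 1, tolerance = 1e-9)
  expect_equal(r$slope_high, 2, tolerance = 1e-9)
  lin2 <- 7 * conc
  names(lin2) <- conc
  r2 <- assess_dimer(lin, lin2)
  expect_equal(r2$label, "not_concentration_dependent")
  mixed <- 5 * conc^1.3
  names(mixed) <- conc
  r3 <- assess_dimer(lin, mixed)
  expect_equal(r3$label, "inconclusive")
  bad <- lin; bad[2] <- -1
  expect_error(assess_dimer(bad, quad), class = "timscreen_invalid_input")
  expect_error(assess_dimer(lin[1:2], quad[1:2]),
               class = "timscreen_insufficient_levels")
})
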