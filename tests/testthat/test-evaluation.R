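test_that("widening the RT window only ever adds annotations", {
  cfg <- tiny_config(seed = 201, n_analytes = 20, n_matrix_features = 0,
                     interference_fraction = 0.5)
  lib <- generate_library(cfg)
  cloud <- generate_peak_cloud(lib, cfg)
  sens <- rt_window_sensitivity(cloud, lib, screening_windows(), CAL,
                                factors = c(1, 2, 5, 10), spectra = NULL)
  expect_equal(sens$factor, c(1, 2, 5, 10))
  expect_true(all(diff(sens$false_positives) >= 0))
  # the factor-1 run is identical to a plain screen
  base <- screen(cloud, lib, screening_windows(), CAL, spectra = NULL)
  expect_identical(as.data.frame(attr(sens, "baseline")), as.data.frame(base))
  expect_error(rt_window_sensitivity(cloud, lib, screening_windows(), CAL,
                                     factors = c(0.5, 1)),
               class = "timscreen_invalid_input")
})

test_that("a tenfold RT window captures exactly the far-shifted interferences", {
  # interferences shifted beyond the 0.25 min window but inside 2.5 min,
  # targeting analytes absent from the sample
  cfg <- tiny_config(seed = 203, n_analytes = 30, n_matrix_features = 0,
                     interference_fraction = 0.6, missing_fraction = 1,
                     interference_rt_offset_range = c(0.35, 2.3))
  lib <- generate_library(cfg)
  cloud <- generate_peak_cloud(lib, cfg)
  truth <- attr(cloud, "truth")
  n_far <- sum(truth$role == "interference")
  expect_gt(n_far, 0)
  sens <- rt_window_sensitivity(cloud, lib, screening_windows(), CAL,
                                factors = c(1, 10), spectra = NULL)
  expect_equal(sens$false_positives[sens$factor == 1], 0L)
  expect_equal(sens$false_positives[sens$factor == 10], n_far)
})

test_that("spectral coverage counts level-1 annotations over matched peaks", {
  ann <- data.frame(
    category = c("true_annotation", "true_annotation", "true_with_interference",
                 "false_positive", "not_detected"),
    confidence_level = c(1L, 4L, 1L, NA, NA),
    ms2_score = c(0.95, 0.2, 0.85, NA, NA))
  cov <- spectral_coverage(ann)
  expect_true(cov$defined)
  expect_equal(cov$coverage_pct, 100 * 2 / 3)
  expect_equal(cov$n_matched, 3L)
  expect_equal(cov$score_summary$median, 0.85)
  # all matched and confirmed
  all1 <- data.frame(category = rep("true_annotation", 4),
                     confidence_level = 1L, ms2_score = 0.9)
  expect_equal(spectral_coverage(all1)$coverage_pct, 100)
  # no matched peaks: explicit undefined signal, not a crash
  none <- data.frame(category = c("false_positive", "not_detected"),
                     confidence_level = NA_integer_, ms2_score = NA_real_)
  cov0 <- spectral_coverage(none)
  expect_false(cov0$defined)
  expect_true(is.na(cov0$coverage_pct))
})

test_that("coverage approaches the event-rate times clean-rate product", {
  # events fire for 80% of precursors; contaminated events (severe, 12.5%
  # of those acquired) fall below the score threshold, so the expected
  # coverage is 0.8 * 0.875 = 70% up to binomial error
  cfg <- scenario_config(seed = 205, n_analytes = 400, n_matrix_features = 0,
                         interference_fraction = 0, missing_fraction = 0,
                         ms2_event_probability = 0.8,
                         ms2_contamination_rate = 0.125,
                         ms2_contamination_intensity = 6)
  lib <- generate_library(cfg)
  cloud <- generate_peak_cloud(lib, cfg)
  ann <- screen(cloud, lib, screening_windows(), CAL)
  cov <- spectral_coverage(ann)
  p <- 0.8 * 0.875
  se <- sqrt(p * (1 - p) / nrow(lib))
  expect_lt(abs(cov$coverage_pct - 100 * p), 100 * 4 * se)
})

test_that("trendline fits recover the generating power laws", {
  # exact power-law input: R^2 = 1 and exact parameters
  mz <- seq(100, 900, length.out = 40)
  exact <- data.frame(mz = rep(mz, 2),
                      ccs = c(24 * mz^0.34, 10.7 * mz^0.56),
                      charge = rep(1:2, each = 40))
  fit <- fit_trendlines(exact)
  expect_equal(fit$r_squared, c(1, 1), tolerance = 1e-12)
  expect_equal(fit$A, c(24, 10.7), tolerance = 1e-9)
  expect_equal(fit$B, c(0.34, 0.56), tolerance = 1e-9)
  # generator truth ledger: parameters recovered within the configured scatter
  cfg <- tiny_config(seed = 207, n_analytes = 50, n_matrix_features = 300,
                     trendline_scatter = 0.03)
  truth <- attr(generate_peak_cloud(generate_library(cfg), cfg), "truth")
  feat <- truth[truth$role %in% c("analyte", "matrix_feature"), ]
  tl <- fit_trendlines(feat[, c("mz", "ccs", "charge")])
  expect_equal(tl$charge, 1:3)
  for (z in 1:3) {
    expect_lt(abs(tl$B[z] - cfg$trendline_B[z]), 0.06)
    expect_lt(abs(log(tl$A[z] / cfg$trendline_A[z])), 0.35)
    expect_gt(tl$r_squared[z], 0.8)
  }
  # sparse charge states are skipped with a notice
  one <- data.frame(mz = c(100, 200, 300, 400), ccs = c(110, 140, 160, 180),
                    charge = c(1, 1, 1, 2))
  expect_message(f1 <- fit_trendlines(one), "skipped")
  expect_equal(f1$charge, 1L)
})

test_that("feature alignment counts shared features one-to-one", {
  cfg <- tiny_config(seed = 209, n_analytes = 40, n_matrix_features = 0)
  truth <- attr(generate_peak_cloud(generate_library(cfg), cfg), "truth")
  tab <- data.frame(mz = truth$mz, rt = truth$rt, ccs = truth$ccs)
  # a table aligned with itself matches completely
  self <- align_features(list(a = tab, b = tab))
  expect_equal(self["a", "b"], nrow(tab))
  expect_equal(self["a", "a"], nrow(tab))
  # disjoint m/z ranges share nothing
  shifted <- transform(tab, mz = mz + 500)
  expect_equal(align_features(list(a = tab, b = shifted))["a", "b"], 0L)
  # a configured 30% overlap is counted exactly
  n <- nrow(tab)
  n_shared <- round(0.3 * n)
  t1 <- tab[seq_len(round(0.65 * n)), ]
  t2 <- rbind(tab[seq_len(n_shared), ], shifted[(n_shared + 1):n, ])
  cnt <- align_features(list(one = t1, two = t2))
  expect_equal(cnt["one", "two"], n_shared)
  expect_equal(cnt["one", "two"], cnt["two", "one"])
  expect_error(align_features(list(tab)), class = "timscreen_invalid_input")
})

test_that("prediction accuracy statistics match their definitions", {
  obs <- c(150.2, 160.8, 171.3, 185.9, 200.1)
  perf <- prediction_accuracy(obs, obs)
  expect_equal(perf$r_squared, 1)
  expect_equal(perf$rmse, 0)
  expect_equal(perf$mae, 0)
  const <- prediction_accuracy(obs, rep(170, 5))
  expect_true(is.na(const$r_squared))
  expect_match(const$note, "constant")
  # RMSE converges to the noise level
  set.seed(211)
  o <- runif(10000, 100, 300)
  p <- o + rnorm(10000, 0, 7.27)
  acc <- prediction_accuracy(o, p)
  expect_lt(abs(acc$rmse - 7.27) / 7.27, 0.03)
  expect_lt(abs(acc$mae - 7.27 * sqrt(2 / pi)) / (7.27 * sqrt(2 / pi)), 0.05)
  expect_error(prediction_accuracy(1:3, 1:4), class = "timscreen_invalid_input")
})

test_that("category counts always partition the library", {
  for (s in c(213, 215)) {
    cfg <- tiny_config(seed = s, n_analytes = 25, interference_fraction = 0.3,
                       missing_fraction = 0.2)
    lib <- generate_library(cfg)
    cloud <- generate_peak_cloud(lib, cfg)
    ann <- screen(cloud, lib, screening_windows(), CAL, spectra = NULL)
    counts <- table(factor(ann$category,
                           c("true_annotation", "true_with_interference",
                             "false_positive", "ambiguous", "not_detected")))
    expect_equal(sum(counts), nrow(lib))
    rep <- evaluation_report(ann)
    expect_equal(Reduce(`+`, rep$category_counts), nrow(lib))
  }
})

test_that("evaluation statistics are pure functions of their inputs", {
  cfg <- tiny_config(seed = 217, n_analytes = 15)
  lib <- generate_library(cfg)
  cloud <- generate_peak_cloud(lib, cfg)
  ann <- screen(cloud, lib, screening_windows(), CAL)
  expect_identical(spectral_coverage(ann), spectral_coverage(ann))
  tl <- attr(cloud, "truth")[, c("mz", "ccs", "charge")]
  expect_identical(fit_trendlines(tl), fit_trendlines(tl))
})
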