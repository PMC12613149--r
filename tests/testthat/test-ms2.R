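make_events <- function(...) {
  ev <- list(...)
  data.frame(precursor_mz = vapply(ev, `[[`, 0, "mz"),
             inv_k0_low = vapply(ev, function(e) e$gate[1], 0),
             inv_k0_high = vapply(ev, function(e) e$gate[2], 0),
             rt_min = vapply(ev, function(e) e$rt %||% 5, 0),
             fragments = I(lapply(ev, `[[`, "frag")))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("gated extraction returns exactly the events inside the gate", {
  fa <- data.frame(mz = c(81.1, 120.5, 150.2), intensity = c(10, 50, 100))
  fb <- data.frame(mz = c(60.3, 95.7), intensity = c(40, 80))
  cloud <- as_cloud(data.frame(rt_min = 5, inv_k0 = 0.8, mz = 300, intensity = 1),
                    ms2_events = make_events(
                      list(mz = 300.0, gate = c(0.79, 0.81), frag = fa),
                      list(mz = 300.2, gate = c(0.99, 1.01), frag = fb)))
  # one matching event: fragments come back unchanged
  sp <- extract_ms2(cloud, 300, c(0.78, 0.82))
  expect_equal(sp$fragments$mz, fa$mz)
  expect_equal(sp$fragments$intensity, fa$intensity)
  # the disjoint gate returns only the second species
  sp2 <- extract_ms2(cloud, 300, c(0.95, 1.05))
  expect_equal(sp2$fragments$mz, fb$mz)
  # ungated request merges both co-isolated species
  sp3 <- extract_ms2(cloud, 300, c(0.45, 1.45))
  expect_equal(nrow(sp3$fragments), 5L)
  # no event in window
  expect_null(extract_ms2(cloud, 300, c(1.2, 1.3)))
  expect_null(extract_ms2(cloud, 500, c(0.45, 1.45)))
  expect_error(extract_ms2(cloud, 300, c(1.3, 1.2)),
               class = "timscreen_invalid_input")
})

test_that("cosine score matches the exhaustive-pairing oracle on toys", {
  set.seed(71)
  for (rep in 1:50) {
    nq <- sample(2:5, 1)
    nr <- sample(2:5, 1)
    # well-separated fragment grids so candidate pairings are unambiguous
    grid <- seq(50, 500, by = 1.7)
    qmz <- sort(sample(grid, nq))
    shared <- sample(nq, sample(0:nq, 1))
    rmz <- sort(c(qmz[shared] + runif(length(shared), -0.004, 0.004),
                  sample(setdiff(grid, qmz), nr)))
    q <- ms2_spectrum(300, data.frame(mz = qmz, intensity = runif(nq, 1, 100)))
    r <- ms2_spectrum(300, data.frame(mz = rmz,
                                      intensity = runif(length(rmz), 1, 100)))
    expect_equal(cosine_score(q, r)$score, cosine_oracle(q, r), tolerance = 1e-12)
  }
})

test_that("cosine score has the expected fixed points and invariances", {
  f <- data.frame(mz = c(80.1, 120.2, 200.5), intensity = c(20, 100, 60))
  a <- ms2_spectrum(300, f)
  expect_equal(cosine_score(a, a)$score, 1)
  b <- ms2_spectrum(300, data.frame(mz = c(90.3, 140.4), intensity = c(50, 50)))
  expect_equal(cosine_score(a, b)$score, 0)
  empty <- ms2_spectrum(300, data.frame(mz = numeric(), intensity = numeric()))
  expect_equal(cosine_score(a, empty)$score, 0)
  set.seed(73)
  for (rep in 1:25) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    s1 <- ms2_spectrum(300, data.frame(mz = runif(n1, 50, 290),
                                       intensity = runif(n1, 1, 100)))
    s2 <- ms2_spectrum(300, data.frame(mz = runif(n2, 50, 290),
                                       intensity = runif(n2, 1, 100)))
    expect_equal(cosine_score(s1, s2)$score, cosine_score(s2, s1)$score)
    s1s <- ms2_spectrum(300, transform(s1$fragments, intensity = intensity * 37.5))
    expect_equal(cosine_score(s1s, s2)$score, cosine_score(s1, s2)$score,
                 tolerance = 1e-12)
    expect_true(cosine_score(s1, s2)$score >= 0 && cosine_score(s1, s2)$score <= 1)
  }
})

test_that("contaminating fragments never raise the score against a clean reference", {
  set.seed(79)
  for (rep in 1:100) {
    n <- sample(3:10, 1)
    ref_mz <- runif(n, 50, 280)
    ref <- ms2_spectrum(300, data.frame(mz = ref_mz, intensity = runif(n, 1, 100)))
    query <- ref
    # a co-isolated species with fragments distinct from the reference's
    m <- sample(2:8, 1)
    cont_mz <- runif(m, 50, 280)
    cont_mz <- cont_mz[vapply(cont_mz, function(x) all(abs(x - ref_mz) > 0.05),
                              logical(1))]
    if (!length(cont_mz)) next
    contaminated <- ms2_spectrum(300, rbind(
      query$fragments,
      data.frame(mz = cont_mz, intensity = runif(length(cont_mz), 1, 150))))
    expect_lte(cosine_score(contaminated, ref)$score,
               cosine_score(query, ref)$score)
  }
})

test_that("mobility gating recovers cleaner spectra than ungated extraction", {
  cfg <- tiny_config(seed = 81, n_analytes = 15, n_matrix_features = 0,
                     interference_fraction = 1, missing_fraction = 0,
                     ms2_event_probability = 1, ms2_contamination_rate = 0)
  lib <- generate_library(cfg)
  cloud <- generate_peak_cloud(lib, cfg)
  truth <- attr(cloud, "truth")
  spectra <- attr(lib, "spectra")
  n_checked <- 0L
  for (i in seq_len(nrow(lib))) {
    a <- truth[truth$role == "analyte" & truth$compound_id == lib$compound_id[i], ]
    it <- truth[truth$role == "interference" &
                  !is.na(truth$target_compound_id) &
                  truth$target_compound_id == lib$compound_id[i], ]
    if (!nrow(a) || !nrow(it)) next
    fw <- a$inv_k0 / cfg$mobility_resolving_power
    ref <- ms2_spectrum(a$mz, spectra[[lib$compound_id[i]]]$fragments)
    gated <- extract_ms2(cloud, lib$mz[i], a$inv_k0 + c(-1, 1) * 1.5 * fw)
    ungated <- extract_ms2(cloud, lib$mz[i], c(0.45, 1.45))
    expect_gt(cosine_score(gated, ref)$score, cosine_score(ungated, ref)$score)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 10L)
})

test_that("confidence levels depend on the spectral match and threshold", {
  ann <- list(category = "true_annotation")
  good <- structure(list(score = 0.9, n_matched_fragments = 5L),
                    class = "spectral_match")
  poor <- structure(list(score = 0.3, n_matched_fragments = 1L),
                    class = "spectral_match")
  expect_equal(assign_confidence(ann, good, 0.7), 1L)
  expect_equal(assign_confidence(ann, poor, 0.7), 4L)
  expect_equal(assign_confidence(ann, NULL, 0.7), 4L)
  expect_equal(assign_confidence(ann, poor, 0.2), 1L)
  expect_error(assign_confidence(list(category = "false_positive"), good),
               class = "timscreen_invalid_state")
  expect_error(assign_confidence(list(category = "not_detected"), NULL),
               class = "timscreen_invalid_state")
})

test_that("MSP files round-trip spectra byte-identically", {
  cfg <- tiny_config(seed = 83, n_analytes = 5)
  spectra <- attr(generate_library(cfg), "spectra")
  p1 <- withr::local_tempfile(fileext = ".msp")
  p2 <- withr::local_tempfile(fileext = ".msp")
  write_msp(spectra, p1)
  back <- read_msp(p1)
  expect_equal(names(back), names(spectra))
  for (nm in names(spectra)) {
    expect_equal(back[[nm]]$precursor_mz, spectra[[nm]]$precursor_mz)
    expect_equal(back[[nm]]$fragments$mz, spectra[[nm]]$fragments$mz)
  }
  write_msp(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(read_msp("/nonexistent/x.msp"), class = "timscreen_io_error")
})
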