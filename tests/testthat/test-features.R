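test_that("relative band powers localize pure tones correctly", {
  w5 <- sine_recording(5, dur_s = 5)$samples[, 1]
  rp <- band_relative_powers(w5, fs_test)
  expect_gte(rp[["rel_power_theta"]], 0.95)
  expect_true(all(rp[names(rp) != "rel_power_theta"] <= 0.05))

  w10 <- sine_recording(10, dur_s = 5)$samples[, 1]
  rp10 <- band_relative_powers(w10, fs_test)
  expect_identical(names(which.max(rp10)), "rel_power_alpha")
  expect_true(all(rp10 >= 0 & rp10 <= 1))
  expect_lte(sum(rp10), 1 + 1e-9)
})

test_that("welch estimator agrees with a brute-force periodogram on tones", {
  for (f0 in c(5, 10, 20, 40)) {
    x <- sine_recording(f0, dur_s = 5)$samples[, 1]
    bd <- band_definitions()
    band <- bd[bd$low <= f0 & bd$high >= f0, ]
    production <- band_relative_powers(x, fs_test)[[paste0("rel_power_",
                                                           band$name)]]
    oracle <- brute_band_fraction(x, fs_test, band$low, band$high)
    expect_equal(production, oracle, tolerance = 0.02)
  }
})

test_that("spectral summaries behave as centroid and mean density", {
  w20 <- sine_recording(20, dur_s = 5)$samples[, 1]
  ss <- spectral_summaries(w20, fs_test)
  expect_lt(abs(ss[["mean_normalized_frequency"]] - 20), 0.5)

  ss2 <- spectral_summaries(2 * w20, fs_test)
  expect_equal(ss2[["average_power"]] / ss[["average_power"]], 4,
               tolerance = 1e-9)
  expect_equal(ss2[["mean_normalized_frequency"]],
               ss[["mean_normalized_frequency"]], tolerance = 1e-9)
})

test_that("white-noise band fractions match bandwidth proportions", {
  set.seed(7)
  n_win <- 120
  rec <- eeg_recording(matrix(rnorm(n_win * 1280), ncol = 1), fs_test)
  tens <- extract_features(segment_recording(rec))
  bd <- band_definitions()
  for (i in seq_len(nrow(bd))) {
    got <- mean(tens$values[, 1, paste0("rel_power_", bd$name[i])])
    # continuum expectation; the 1-Hz Welch bin grid shifts each band by
    # up to one bin's worth of power
    expected <- (bd$high[i] - bd$low[i]) / 89.5
    expect_lt(abs(got - expected), 0.015)
  }
  centroid <- mean(tens$values[, 1, "mean_normalized_frequency"])
  expect_equal(centroid, (0.5 + 90) / 2, tolerance = 1.5)
})

test_that("amplitude statistics match closed forms", {
  sq <- rep(c(3, -3), each = 640)
  as_sq <- amplitude_stats(sq)
  expect_equal(as_sq[["normalized_mean_amplitude"]], 1)

  z <- amplitude_stats(rep(0, 1280))
  expect_equal(unname(z[1:3]), c(0, 0, 0))
  expect_true(attr(z, "degenerate"))

  A <- 2.5
  s <- A * sin(2 * pi * 5 * seq(0, 5 - 1 / fs_test, by = 1 / fs_test))
  as_s <- amplitude_stats(s)
  expect_equal(as_s[["mean_amplitude"]], 2 * A / pi, tolerance = 1e-3)
  expect_equal(as_s[["normalized_mean_amplitude"]], 2 / pi,
               tolerance = 1e-3)
})

test_that("feature tensor composes single-window operations consistently", {
  set.seed(21)
  rec <- eeg_recording(matrix(rnorm(1280 * 3 * 2), ncol = 2), fs_test,
                       c("T3", "Cz"))
  w <- segment_recording(rec)
  tens <- extract_features(w)
  expect_identical(dim(tens$values), c(3L, 2L, 12L))
  expect_identical(dimnames(tens$values)[[3]], feature_names())

  x <- get_window(w, 2, "Cz")
  expect_equal(tens$values[2, "Cz", 1:7],
               band_relative_powers(x, fs_test)[1:7], ignore_attr = TRUE)
  expect_equal(tens$values[2, "Cz", 10:12],
               amplitude_stats(x)[1:3], ignore_attr = TRUE)

  # scale equivariance: relative powers invariant, amplitudes scale
  rec2 <- eeg_recording(3 * rec$samples, fs_test, c("T3", "Cz"))
  tens2 <- extract_features(segment_recording(rec2))
  expect_equal(tens2$values[, , 1:7], tens$values[, , 1:7],
               tolerance = 1e-9)
  expect_equal(tens2$values[, , "mean_amplitude"],
               3 * tens$values[, , "mean_amplitude"], tolerance = 1e-9)
  expect_equal(tens2$values[, , "amplitude_variance"],
               9 * tens$values[, , "amplitude_variance"], tolerance = 1e-9)
})

test_that("feature tensors persist as flat tables", {
  tens <- fake_tensor(4, planted_electrode = "T3",
                      planted_feature = "rel_power_theta", fill = 0.7)
  path <- file.path(tempdir(), "tensor.csv")
  write_feature_tensor(tens, path)
  back <- read_feature_tensor(path, sampling_rate = fs_test)
  expect_equal(back$values, tens$values, tolerance = 1e-12)
  expect_equal(back$window_start_times, tens$window_start_times)
})
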