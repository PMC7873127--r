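small_cfg <- function(...) {
  synth_config(n_channels = 2L, seizure_onsets = 1500, duration_s = 1560,
               signature_electrodes = "Fp1", signature_band = "theta",
               signature_onset = 15, ...)
}

theta_separation <- function(cfg, electrode = "Fp1") {
  out <- generate_recording(cfg)
  tens <- extract_features(segment_recording(out$recording))
  t <- tens$window_start_times
  onset <- cfg$seizure_onsets[1]
  planted <- t >= onset - cfg$signature_onset * 60 & t < onset
  inter <- t < onset - cfg$signature_onset * 60
  mean(tens$values[planted, electrode, "rel_power_theta"]) -
    mean(tens$values[inter, electrode, "rel_power_theta"])
}

test_that("equal seeds give bit-identical recordings", {
  cfg <- small_cfg(effect_size = 2, seed = 77)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth$seizures, b$truth$seizures)
  cfg2 <- small_cfg(effect_size = 2, seed = 78)
  expect_false(identical(generate_recording(cfg2)$recording$samples,
                         a$recording$samples))
})

test_that("invalid configurations are rejected with diagnostics", {
  expect_error(synth_config(seizure_onsets = c(2000, 1000)),
               "strictly increasing")
  expect_error(synth_config(signature_onset = 0), "signature_onset")
  expect_error(small_cfg(effect_size = -1), "effect_size")
  expect_error(synth_config(n_channels = 2,
                            signature_electrodes = "T3"),
               "subset")
  # consecutive onsets with overlapping pre-ictal windows
  expect_error(synth_config(n_channels = 2, signature_onset = 10,
                            seizure_onsets = c(3600, 3900)),
               "overlapping")
  expect_error(small_cfg(seed = 1, duration_s = 100), "duration_s")
})

test_that("ground truth places the pre-ictal start before its onset", {
  out <- generate_recording(small_cfg(effect_size = 2, seed = 79))
  tr <- out$truth$seizures
  expect_true(all(tr$preictal_start_s < tr$onset_s))
  expect_equal(out$recording$onsets, tr$onset_s)
})

test_that("a planted theta signature raises theta relative power", {
  cfg <- synth_config(n_channels = 8L, seizure_onsets = 1500,
                      duration_s = 1560, signature_electrodes = "T3",
                      signature_band = "theta", signature_onset = 15,
                      effect_size = 2, seed = 80)
  out <- generate_recording(cfg)
  tens <- extract_features(segment_recording(out$recording))
  t <- tens$window_start_times
  planted <- t >= 600 & t < 1500
  inter <- t < 600
  expect_gt(mean(tens$values[planted, "T3", "rel_power_theta"]),
            mean(tens$values[inter, "T3", "rel_power_theta"]))
  # control channel far from the signature stays flat
  ctrl <- mean(tens$values[planted, "Fp2", "rel_power_theta"]) -
    mean(tens$values[inter, "Fp2", "rel_power_theta"])
  expect_lt(abs(ctrl), 0.05)
})

test_that("without signal the planted window is indistinguishable", {
  ps <- vapply(1:6, function(s) {
    out <- generate_recording(small_cfg(effect_size = 1, seed = 200 + s))
    tens <- extract_features(segment_recording(out$recording))
    t <- tens$window_start_times
    planted <- t >= 600 & t < 1500
    x <- tens$values[planted, "Fp1", "rel_power_theta"]
    y <- tens$values[t < 600, "Fp1", "rel_power_theta"]
    t.test(x, y)$p.value
  }, numeric(1))
  expect_lte(sum(ps < 0.05), 2)
})

test_that("mean separation of the planted feature grows with effect size", {
  seeds <- 1:5
  sep <- vapply(c(1, 1.6, 2.4), function(eff)
    mean(vapply(seeds, function(s)
      theta_separation(synth_config(n_channels = 2L,
                                    seizure_onsets = 900,
                                    duration_s = 960,
                                    signature_electrodes = "Fp1",
                                    signature_onset = 10,
                                    effect_size = eff,
                                    seed = 300 + s)),
      numeric(1))), numeric(1))
  expect_lt(abs(sep[1]), 0.03)
  expect_true(all(diff(sep) > 0))
})

test_that("generator configurations round-trip through key: value files", {
  cfg <- small_cfg(effect_size = 1.8, seed = 91)
  path <- file.path(tempdir(), "synth.yml")
  write_synth_config(cfg, path)
  back <- read_synth_config(path)
  expect_equal(back[names(back) != "channel_labels"],
               cfg[names(cfg) != "channel_labels"], ignore_attr = TRUE)
  writeLines("nonsense_key: 1", path)
  expect_error(read_synth_config(path), "unknown generator")
})

test_that("patient datasets land on disk with the promised layout", {
  # a strong effect, so the signature check is not swamped by the slow
  # band-power fluctuations intrinsic to 1/f backgrounds over 4-h records
  cfg <- synth_config(n_channels = 2L, signature_electrodes = "Fp1",
                      signature_onset = 30, effect_size = 2.5, seed = 81)
  expect_error(generate_patient(cfg, 1, 1, tempdir()), "at least 2")

  dir <- file.path(tempdir(), "patient81")
  man <- generate_patient(cfg, 3, 2, dir)
  expect_setequal(basename(man$files),
                  c("train_01.edf", "train_02.edf", "train_03.edf",
                    "test.edf"))
  # 4-h training segments: header 256 * (1 + ns) plus 16-bit samples
  fs <- 256; ns <- 2
  expected_train <- 256 * (1 + ns) + 2 * ns * fs * 14400
  for (f in man$files[1:3])
    expect_identical(file.info(f)$size, expected_train)

  ann <- read.csv(file.path(dir, "annotations.csv"))
  expect_equal(ann$onset_s[ann$segment_id == "test"], c(7200, 14400))
  expect_equal(ann$onset_s[grepl("^train", ann$segment_id)],
               rep(14400, 3))
  # chronological ordering encoded in segment ids
  expect_identical(sort(unique(ann$segment_id)),
                   c("test", "train_01", "train_02", "train_03"))

  truth <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_true(all(truth$band == "theta"))

  # the planted signature survives the disk round trip (feature level)
  rec <- read_recording(file.path(dir, "train_01.edf"),
                        expected_rate = fs)
  tens <- extract_features(segment_recording(rec))
  t <- tens$window_start_times
  planted <- t >= 14400 - 1800 & t < 14400
  inter <- t < 14400 - 1800 - 3600
  expect_gt(mean(tens$values[planted, "Fp1", "rel_power_theta"]),
            mean(tens$values[inter, "Fp1", "rel_power_theta"]))
})
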