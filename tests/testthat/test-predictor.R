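test_that("hyper-feature series aggregate the tensor as specified", {
  dom <- tiny_domains()
  set.seed(4)
  ind <- random_individual(dom)
  for (i in 1:5) {
    ind$hyper_features[[i]]$electrode <- "Fp1"
    ind$hyper_features[[i]]$time_instant <- "0"
    ind$hyper_features[[i]]$window_length <- "1"
    ind$hyper_features[[i]]$math_operator <- "mean"
  }
  ph <- decode_individual(ind, 40)

  # constant tensor + mean -> constant series; variance -> 0
  tens_c <- fake_tensor(720, electrodes = c("Fp1", "Fp2"), baseline = 0.37)
  s <- build_series(tens_c, ph, onsets = 3600)
  expect_true(all(abs(s$X - 0.37) < 1e-12))
  ind2 <- ind
  for (i in 1:5) ind2$hyper_features[[i]]$math_operator <- "variance"
  s2 <- build_series(tens_c, decode_individual(ind2, 40), onsets = 3600)
  expect_true(all(abs(s2$X) < 1e-12))

  # w = 1 min, t = 0: value at r is the mean of the 12 windows ending at r
  tens_r <- fake_tensor(720, electrodes = c("Fp1", "Fp2"), noise_sd = 0.1,
                        seed = 9)
  sr <- build_series(tens_r, ph, onsets = 3600)
  r <- sr$times[5]
  idx <- (r / 5 - 11):(r / 5)
  expect_equal(unname(sr$X[5, 1]),
               mean(tens_r$values[idx, "Fp1",
                                  ph$recipes$feature[1]]), tolerance = 1e-12)

  # labels follow the decoded pre-ictal geometry
  onset <- 3600
  lab <- sr$labels
  pre_rows <- sr$times >= onset - ph$pre_ictal_min * 60 &
    sr$times < onset - 600
  expect_true(all(lab[pre_rows] == "preictal"))
  expect_true(all(lab[sr$times < onset - ph$pre_ictal_min * 60] ==
                    "interictal"))
  expect_true(all(lab[sr$times >= onset - 600] == "excluded"))
})

test_that("time-instant offsets shift the aggregation window backwards", {
  dom <- tiny_domains()
  set.seed(14)
  ind <- random_individual(dom)
  for (i in 1:5) {
    ind$hyper_features[[i]]$electrode <- "Fp1"
    ind$hyper_features[[i]]$window_length <- "1"
    ind$hyper_features[[i]]$math_operator <- "mean"
    ind$hyper_features[[i]]$time_instant <- "0"
  }
  ind$hyper_features[[2]]$time_instant <- "3"
  ph <- decode_individual(ind, 40)
  tens <- fake_tensor(720, electrodes = c("Fp1", "Fp2"), noise_sd = 0.1,
                      seed = 10)
  s <- build_series(tens, ph, onsets = 3600)
  r <- s$times[8]
  idx <- ((r - 180) / 5 - 11):((r - 180) / 5)
  expect_equal(unname(s$X[8, 2]),
               mean(tens$values[idx, "Fp1", ph$recipes$feature[2]]),
               tolerance = 1e-12)
})

test_that("lag expansion replicates columns at 1-3 min delays", {
  X <- matrix(rnorm(50 * 5), ncol = 5,
              dimnames = list(NULL, paste0("hf", 1:5)))
  s <- fake_series(X, rep("interictal", 50), onsets = numeric(0),
                   pre_ictal_min = 40)
  sl <- add_lags(s)
  expect_identical(ncol(sl$X), 20L)
  expect_identical(nrow(sl$X), 47L)
  expect_equal(unname(sl$X[10, "hf2_lag1"]), unname(X[12, "hf2"]))
  expect_equal(unname(sl$X[10, "hf4_lag3"]), unname(X[10, "hf4"]))
  expect_equal(unname(sl$X[, "hf1_lag0"]), unname(X[4:50, "hf1"]))

  short <- fake_series(X[1:3, , drop = FALSE], rep("interictal", 3),
                       numeric(0), 40)
  expect_error(add_lags(short), "longer than the largest lag")
})

test_that("the correlation filter drops redundant columns greedily", {
  set.seed(6)
  x <- rnorm(300)
  X <- cbind(a = x, b = x, c = -x, d = rnorm(300), e = rnorm(300))
  expect_identical(correlation_filter(X), c(1L, 4L, 5L))

  Xz <- cbind(a = x, z = rep(1, 300))
  expect_warning(keep <- correlation_filter(Xz), "zero-variance")
  expect_identical(keep, 1L)

  Xn <- matrix(rnorm(500 * 8), ncol = 8)
  expect_identical(correlation_filter(Xn), 1:8)
})

test_that("the classifier is class-weighted, standardized and leak-free", {
  # perfectly separable 1-D set
  X <- matrix(c(-2, -1.5, -1, 1, 1.5, 2), ncol = 1,
              dimnames = list(NULL, "hf1_lag0"))
  lab <- c(rep("interictal", 3), rep("preictal", 3))
  m <- fit_classifier(X, lab)
  expect_true(all((predict_probability(m, X) > 0.5) == (lab == "preictal")))
  expect_equal(unname(m$center), mean(X))

  expect_error(fit_classifier(X, rep("interictal", 6)), "single class")

  # inverse-frequency weighting: duplicating the minority class leaves the
  # decision boundary (sign of the probability - 0.5) unchanged
  set.seed(13)
  X2 <- matrix(c(rnorm(40, -1), rnorm(10, 1)), ncol = 1,
               dimnames = list(NULL, "hf1_lag0"))
  lab2 <- c(rep("interictal", 40), rep("preictal", 10))
  m1 <- fit_classifier(X2, lab2)
  X2d <- rbind(X2, X2[41:50, , drop = FALSE])
  lab2d <- c(lab2, rep("preictal", 10))
  m2 <- fit_classifier(X2d, lab2d)
  grid <- matrix(seq(-3, 3, by = 0.1), ncol = 1,
                 dimnames = list(NULL, "hf1_lag0"))
  p1 <- predict_probability(m1, grid)
  p2 <- predict_probability(m2, grid)
  expect_equal(mean((p1 > 0.5) == (p2 > 0.5)), 1)
})

test_that("the logistic probability matches a direct sigmoid computation", {
  set.seed(17)
  cols <- paste0("hf", 1:4, "_lag0")
  beta <- rnorm(4)
  m <- fake_model(cols, beta, beta0 = 0.3)
  X <- matrix(rnorm(200 * 4), ncol = 4, dimnames = list(NULL, cols))
  p <- predict_probability(m, X)
  oracle <- stats::plogis(0.3 + drop(X %*% beta))
  expect_lt(max(abs(p - oracle)), 1e-12)
  m0 <- fake_model(cols, rep(0, 4), beta0 = 0)
  expect_true(all(predict_probability(m0, X) == 0.5))
})

test_that("firing power is the trailing moving mean with warm-up", {
  expect_true(all(firing_power(rep(1, 30), 10) == 1))
  expect_true(all(firing_power(rep(0, 30), 10) == 0))
  fp_alt <- firing_power(rep(c(0, 1), 20), 10)
  expect_true(all(fp_alt[10:40] == 0.5))
  set.seed(19)
  x <- rbinom(120, 1, 0.4)
  expect_equal(firing_power(x, 37), brute_moving_mean(x, 37),
               tolerance = 1e-12)
})

test_that("alarms fire on upward crossings and honour refractory periods", {
  times <- (1:100) * 60
  expect_identical(length(trigger_alarms(rep(0.69, 100), times)$times), 0L)

  fp <- rep(0.2, 100); fp[40:45] <- 0.9
  a <- trigger_alarms(fp, times)
  expect_equal(a$times, 40 * 60)

  # two crossings 10 min apart under a 55-min refractory: one alarm
  fp2 <- rep(0.2, 100); fp2[30] <- 0.9; fp2[40] <- 0.9
  a2 <- trigger_alarms(fp2, times, refractory_min = 55)
  expect_equal(a2$times, 30 * 60)
  expect_equal(unname(a2$refractory[1, ]), c(30 * 60, 30 * 60 + 55 * 60))
  a3 <- trigger_alarms(fp2, times)
  expect_equal(a3$times, c(30, 40) * 60)
})

test_that("the composite performance follows its defining arithmetic", {
  expect_identical(performance_score(1, 1, 0, 0), 1)
  expect_identical(performance_score(0, 0, 0, 0), 0)
  expect_equal(performance_score(0.8, 1, 0.2, 0.1), 0.68)
  # bounded above by 1
  set.seed(23)
  for (i in 1:200) {
    v <- performance_score(runif(1), runif(1), rexp(1), runif(1))
    expect_lte(v, 1)
  }
})

test_that("seizure evaluation computes rates, alarms and the FPR/h denominator", {
  # craft outputs via a sign model: p > 0.5 iff x > 0
  n <- 200
  onset <- (n + 5) * 60
  times <- (1:n) * 60
  pre <- times >= onset - 50 * 60 & times < onset - 10 * 60
  labels <- ifelse(pre, "preictal", "interictal")
  labels[times >= onset - 600] <- "excluded"
  x <- ifelse(pre, 1, -1)
  # misclassify the first 10% of pre-ictal rows; the remaining streak of
  # 36 pre-ictal hits pushes the 50-min firing power past 0.70 in time
  flip <- which(pre)[seq_len(round(0.1 * sum(pre)))]
  x[flip] <- -1
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "hf1_lag0"))
  m <- fake_model("hf1_lag0", 10)
  s <- fake_series(X, labels, onsets = onset, pre_ictal_min = 50,
                   times = times)
  ev <- evaluate_seizure(s, m, mode = "fitness")
  expect_equal(ev$s_s, 0.9, tolerance = 1e-9)
  expect_equal(ev$t_f, 0)
  expect_equal(ev$fpr_h, 0)
  expect_equal(ev$s_p, 1)
  expect_equal(ev$performance, 0.95, tolerance = 1e-9)

  # a lone inter-ictal burst makes a false alarm; test mode removes the
  # refractory span from the denominator
  x2 <- ifelse(pre, 1, -1)
  x2[30:70] <- 1    # long inter-ictal burst -> firing power crosses 0.7
  s2 <- fake_series(matrix(x2, ncol = 1,
                           dimnames = list(NULL, "hf1_lag0")),
                    labels, onsets = onset, pre_ictal_min = 50,
                    times = times)
  ev2 <- evaluate_seizure(s2, m, mode = "test")
  expect_gte(length(ev2$alarms$times), 1)
  expect_equal(ev2$n_false, 1)
  n_inter <- sum(labels == "interictal")
  in_refr <- sum(labels == "interictal" &
                   times > ev2$alarms$refractory[1, 1] &
                   times <= ev2$alarms$refractory[1, 2])
  expect_equal(ev2$inter_hours, (n_inter - in_refr) / 60, tolerance = 1e-9)
  expect_equal(ev2$fpr_h, 1 / ev2$inter_hours, tolerance = 1e-9)
})

test_that("iterative fitness retrains per seizure and is cache-consistent", {
  pat <- fake_patient(n_train = 3)
  dom <- gene_domains(electrodes = pat$electrodes)
  set.seed(31)
  matched <- random_individual(dom)
  for (i in 1:5) {
    matched$hyper_features[[i]]$dominant_feature <- "band_wave"
    matched$hyper_features[[i]]$band_wave_feature <- "rel_power_theta"
    matched$hyper_features[[i]]$electrode <- "T3"
    matched$hyper_features[[i]]$math_operator <- "mean"
    matched$hyper_features[[i]]$time_instant <- "0"
    matched$hyper_features[[i]]$window_length <-
      as.character(c(1, 5, 10, 1, 5)[i])
  }
  f1 <- evaluate_fitness(matched, pat, 40)
  f2 <- evaluate_fitness(matched, pat, 40)
  expect_identical(f1, f2)
  expect_gt(f1, 0.4)

  # k = 2: fitness equals the single held-out seizure's performance
  pat2 <- fake_patient(n_train = 2)
  phen <- decode_individual(matched, 40)
  d1 <- add_lags(build_series(pat2$train[[1]]$tensor, phen,
                              pat2$train[[1]]$onsets))
  d2 <- add_lags(build_series(pat2$train[[2]]$tensor, phen,
                              pat2$train[[2]]$onsets))
  keep <- d1$labels != "excluded"
  model <- suppressWarnings(fit_classifier(d1$X[keep, ], d1$labels[keep]))
  direct <- evaluate_seizure(d2, model, mode = "fitness")$performance
  expect_equal(evaluate_fitness(matched, pat2, 40), direct,
               tolerance = 1e-12)

  # an unfittable phenotype earns the sentinel fitness
  broken <- pat
  broken$train <- lapply(broken$train, function(s) {
    s$tensor$values[] <- 0.5
    s
  })
  broken$cache <- new.env(parent = emptyenv())
  expect_identical(evaluate_fitness(matched, broken, 40), -10)
})

test_that("prospective testing predicts the planted seizure above chance", {
  pat <- fake_patient(n_train = 3, effect = 0.5, noise_sd = 0.02)
  dom <- gene_domains(electrodes = pat$electrodes)
  set.seed(37)
  matched <- random_individual(dom)
  for (i in 1:5) {
    matched$hyper_features[[i]]$dominant_feature <- "band_wave"
    matched$hyper_features[[i]]$band_wave_feature <- "rel_power_theta"
    matched$hyper_features[[i]]$electrode <- "T3"
    matched$hyper_features[[i]]$math_operator <-
      c("mean", "mean", "median", "max", "mean")[i]
    matched$hyper_features[[i]]$time_instant <- "0"
    matched$hyper_features[[i]]$window_length <-
      as.character(c(1, 5, 10, 1, 5)[i])
  }
  out <- evaluate_test(matched, pat, 40)
  expect_s3_class(out$metrics, "perf_metrics")
  expect_equal(out$metrics$s_p, 1)
  expect_identical(length(out$metrics$per_seizure),
                   length(pat$test$onsets))
  # z-score parameters come from training rows only
  phen <- decode_individual(matched, 40)
  tr_designs <- lapply(seq_along(pat$train), function(j)
    add_lags(build_series(pat$train[[j]]$tensor, phen,
                          pat$train[[j]]$onsets)))
  Xtr <- do.call(rbind, lapply(tr_designs, function(d)
    d$X[d$labels != "excluded", , drop = FALSE]))
  expect_equal(out$model$center,
               colMeans(Xtr[, out$model$retained, drop = FALSE]),
               tolerance = 1e-12)
})
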