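# Programmatic fixtures: tiny recordings and hand-built feature tensors /
# models, so predictor logic is testable without hours of synthetic EEG.

fs_test <- 256

sine_recording <- function(freq, dur_s = 30, fs = fs_test, amp = 1,
                           channels = 1L) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  eeg_recording(matrix(rep(amp * sin(2 * pi * freq * t), channels),
                       ncol = channels),
                fs, paste0("ch", seq_len(channels)))
}

# feature tensor with controlled content: `fill` is either a single number
# or a function(window_index) for the planted electrode/feature; all other
# cells hold `baseline` plus optional noise
fake_tensor <- function(n_windows, electrodes = c("T3", "Cz"),
                        planted_electrode = NULL, planted_feature = NULL,
                        fill = NULL, baseline = 0.2, noise_sd = 0,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fn <- feature_names()
  vals <- array(baseline, dim = c(n_windows, length(electrodes), 12L),
                dimnames = list(NULL, electrodes, fn))
  if (noise_sd > 0)
    vals <- vals + array(rnorm(length(vals), sd = noise_sd), dim = dim(vals))
  if (!is.null(planted_electrode)) {
    v <- if (is.function(fill)) fill(seq_len(n_windows)) else fill
    vals[, planted_electrode, planted_feature] <- v
  }
  structure(list(values = vals, feature_names = fn,
                 window_start_times = (seq_len(n_windows) - 1) * 5,
                 window_s = 5, sampling_rate = fs_test,
                 electrodes = electrodes,
                 degenerate = matrix(FALSE, n_windows, length(electrodes))),
            class = "feature_tensor")
}

# patient whose tensors carry a separable pre-ictal rise of one feature on
# one electrode; n_windows = 1080 gives 90-min segments
fake_patient <- function(n_train = 2, n_windows = 1080,
                         electrodes = c("T3", "Cz"),
                         planted_electrode = "T3",
                         planted_feature = "rel_power_theta",
                         effect = 0.3, noise_sd = 0.02, seed = 42,
                         test_windows = 2160, test_onsets = 5400 + 5 * test_windows %/% 2) {
  set.seed(seed)
  onset_s <- n_windows * 5
  # drift begins 60 min before onset, preceding the 40-min labelled
  # pre-ictal boundary so firing-power alarms can fall inside the SOP
  ramp <- function(onsets, n) {
    v <- rep(0, n)
    t <- (seq_len(n) - 1) * 5
    for (o in onsets) {
      idx <- t >= o - 3600 & t < o
      v[idx] <- effect * (t[idx] - (o - 3600)) / 3600
    }
    v
  }
  mk <- function(n, onsets) {
    tens <- fake_tensor(n, electrodes, noise_sd = noise_sd)
    tens$values[, planted_electrode, planted_feature] <-
      0.2 + ramp(onsets, n) + rnorm(n, sd = noise_sd)
    list(tensor = tens, onsets = onsets, duration_s = n * 5)
  }
  structure(list(train = lapply(seq_len(n_train), function(i)
    mk(n_windows, onset_s)),
    test = mk(test_windows, test_onsets),
    electrodes = electrodes,
    cache = new.env(parent = emptyenv())),
    class = "patient_data")
}

# hand-built logistic model over given retained columns
fake_model <- function(retained, beta, beta0 = 0,
                       center = NULL, scale = NULL) {
  structure(list(beta0 = beta0,
                 beta = stats::setNames(beta, retained),
                 center = stats::setNames(center %||%
                                            rep(0, length(retained)),
                                          retained),
                 scale = stats::setNames(scale %||%
                                           rep(1, length(retained)),
                                         retained),
                 retained = retained, n_features = length(retained),
                 converged = TRUE),
            class = "hf_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built lag-free series (X a matrix with hf columns, labels given)
fake_series <- function(X, labels, onsets, pre_ictal_min, sph_min = 10,
                        times = NULL) {
  structure(list(times = times %||% (seq_len(nrow(X)) * 60),
                 X = X, labels = labels, onsets = onsets,
                 pre_ictal_min = pre_ictal_min,
                 sop_min = pre_ictal_min - sph_min, sph_min = sph_min),
            class = "hf_series")
}

# hidden-target benchmark fitness, graded per gene by neighbourhood-graph
# distance (additive and monotone, optimum exactly at the target genotype)
graded_target_fitness <- function(domains, target) {
  dist_tables <- lapply(domains$genes, function(gd) {
    k <- length(gd$values)
    t(vapply(seq_len(k), function(u) bfs_distances(gd$adjacency, u),
             integer(k)))
  })
  d_max <- sum(vapply(dist_tables, max, integer(1)))
  tgt <- lapply(target$hyper_features, function(h)
    vapply(names(domains$genes), function(g)
      match(h[[g]], domains$genes[[g]]$values), integer(1)))
  function(ind) {
    tot <- 0L
    for (i in 1:5) {
      h <- ind$hyper_features[[i]]
      for (g in names(domains$genes))
        tot <- tot + dist_tables[[g]][match(h[[g]],
                                            domains$genes[[g]]$values),
                                      tgt[[i]][g]]
    }
    1 - tot / (5 * d_max)
  }
}

tiny_domains <- function() {
  gene_domains(electrodes = c("Fp1", "Fp2", "F7", "F3"),
               window_lengths = c(1, 5), time_instants = 0:5)
}
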