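# Synthetic scalp-EEG generator with plantable pre-ictal signatures.
#
# Background model per channel: 1/f^gamma noise plus a low-amplitude alpha
# oscillation plus an independent band-limited noise component in the
# signature band. On signature electrodes the band component's amplitude is
# ramped linearly from 1x to effect_size x across the planted pre-ictal
# window, emulating a gradual pre-ictal band-power drift. Ictal activity is
# not modelled beyond a flagged 60-s placeholder burst at onset (the
# prediction method never uses ictal samples).

# evaluate expr under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration of the synthetic EEG generator
#'
#' @param n_channels number of channels; labelled with the first
#'   `n_channels` 10-20 electrodes (default 19, the full montage).
#' @param sampling_rate Hz (default 256).
#' @param seizure_onsets seconds from record start, strictly increasing.
#' @param signature_electrodes channel labels that carry the planted
#'   pre-ictal drift (empty = no planted electrodes).
#' @param signature_band one of the seven analysis bands (default "theta").
#' @param signature_onset minutes before each seizure at which the drift
#'   begins (default 60: the drift must precede the earliest labelled
#'   pre-ictal boundary, because the Firing Power needs about 0.7 x
#'   pre-ictal-period minutes of pre-ictal classifications before it can
#'   raise an alarm inside the seizure occurrence period).
#' @param effect_size multiplicative amplitude gain reached at seizure
#'   onset; 1.0 means no signal.
#' @param noise_exponent slope gamma of the 1/f^gamma background.
#' @param duration_s record length; default extends 120 s past the last
#'   onset (or 600 s total when there are no onsets).
#' @param background_rms,alpha_amplitude,band_rms amplitude scales in
#'   microvolts for the three signal components.
#' @param ictal_burst plant a flagged 60-s 3-Hz placeholder burst at each
#'   onset (default TRUE).
#' @param seed integer RNG seed; equal seeds give bit-identical records.
#' @return a validated `synth_config`.
#' @export
synth_config <- function(n_channels = 19L,
                         sampling_rate = 256,
                         seizure_onsets = numeric(0),
                         signature_electrodes = character(0),
                         signature_band = "theta",
                         signature_onset = 60,
                         effect_size = 1.0,
                         noise_exponent = 1.0,
                         duration_s = NULL,
                         background_rms = 30,
                         alpha_amplitude = 10,
                         band_rms = 8,
                         ictal_burst = TRUE,
                         seed = NULL) {
  labels <- montage_1020()[seq_len(n_channels)]
  if (length(seizure_onsets) > 1L && any(diff(seizure_onsets) <= 0))
    stop("seizure onsets must be strictly increasing")
  if (!signature_band %in% band_definitions()$name)
    stop("signature_band must be one of: ",
         paste(band_definitions()$name, collapse = ", "))
  if (!all(signature_electrodes %in% labels))
    stop("signature_electrodes must be a subset of the channel labels")
  if (signature_onset <= 0) stop("signature_onset must be > 0")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (is.null(duration_s))
    duration_s <- if (length(seizure_onsets))
      max(seizure_onsets) + 120 else 600
  if (length(seizure_onsets) && min(seizure_onsets) < signature_onset * 60)
    stop("first seizure onset leaves no room for its pre-ictal window")
  if (length(seizure_onsets) > 1L) {
    gap_ok <- diff(seizure_onsets) > signature_onset * 60 + 60
    if (!all(gap_ok))
      stop("overlapping pre-ictal windows: consecutive onsets must be more ",
           "than signature_onset + 1 min apart")
  }
  if (max(c(seizure_onsets, 0)) > duration_s)
    stop("duration_s shorter than the last seizure onset")
  structure(list(n_channels = as.integer(n_channels),
                 channel_labels = labels,
                 sampling_rate = sampling_rate,
                 seizure_onsets = as.numeric(seizure_onsets),
                 signature_electrodes = signature_electrodes,
                 signature_band = signature_band,
                 signature_onset = signature_onset,
                 effect_size = effect_size,
                 noise_exponent = noise_exponent,
                 duration_s = duration_s,
                 background_rms = background_rms,
                 alpha_amplitude = alpha_amplitude,
                 band_rms = band_rms,
                 ictal_burst = ictal_burst,
                 seed = seed),
            class = "synth_config")
}

# spectrally shaped unit-RMS noise, two independent channels per complex
# FFT (the shape is real and symmetric, so real and imaginary parts stay
# independent). Returns an n x 2 matrix.
shaped_noise_pair <- function(n, shape, nfft) {
  # the spectrum of complex white noise is complex white noise, so the
  # Gaussian spectrum is drawn directly and only one (inverse) FFT is needed
  z <- complex(real = stats::rnorm(nfft), imaginary = stats::rnorm(nfft))
  y <- stats::fft(z * shape, inverse = TRUE) / sqrt(nfft)
  cbind(Re(y)[seq_len(n)] / stats::sd(Re(y)[seq_len(n)]),
        Im(y)[seq_len(n)] / stats::sd(Im(y)[seq_len(n)]))
}

# folded frequency axis of an nfft-point FFT
fft_freqs <- function(nfft, fs) {
  f <- (seq_len(nfft) - 1L) * fs / nfft
  pmin(f, fs - f)
}

# 1/f^gamma spectral shape (DC removed)
pink_shape <- function(nfft, gamma, fs) {
  if (gamma == 0) return(rep(1, nfft))
  f <- fft_freqs(nfft, fs)
  c(0, f[-1]^(-gamma / 2))
}

# 4th-order Butterworth band-pass magnitude shape
band_shape <- function(nfft, band, fs) {
  bf <- signal::butter(2, c(band[1], band[2]) / (fs / 2), type = "pass")
  sqrt(iir_power_gain(bf$b, bf$a, fft_freqs(nfft, fs), fs))
}

# single-channel conveniences (used by tests and small fixtures)
pink_noise <- function(n, gamma, fs) {
  nfft <- stats::nextn(n, factors = c(2, 3, 5))
  shaped_noise_pair(n, pink_shape(nfft, gamma, fs), nfft)[, 1L]
}

band_noise <- function(n, band, fs) {
  nfft <- stats::nextn(n, factors = c(2, 3, 5))
  shaped_noise_pair(n, band_shape(nfft, band, fs), nfft)[, 1L]
}

#' Read / write a generator configuration as a key: value text file
#'
#' YAML with one key per [synth_config()] argument; unknown keys are
#' rejected. Round trip: `write_synth_config()` then `read_synth_config()`
#' reproduces the configuration.
#'
#' @param path text file path.
#' @return `read_synth_config` returns a validated `synth_config`;
#'   `write_synth_config` returns `path` invisibly.
#' @export
read_synth_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(synth_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad))
    stop("unknown generator configuration key(s): ",
         paste(bad, collapse = ", "))
  do.call(synth_config, vals)
}

#' @rdname read_synth_config
#' @param config a `synth_config`.
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  keep <- intersect(names(config), names(formals(synth_config)))
  yaml::write_yaml(config[keep], path)
  invisible(path)
}

#' Generate a synthetic EEG recording with known ground truth
#'
#' @param config a [synth_config()].
#' @return list with `recording` (an `eeg_recording`) and `truth`
#'   (a `ground_truth`: data.frame of onsets and planted pre-ictal starts,
#'   plus the affected electrodes and band).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    fs <- config$sampling_rate
    n <- as.integer(round(config$duration_s * fs))
    t <- (seq_len(n) - 1) / fs
    bd <- band_definitions()
    band <- unlist(bd[bd$name == config$signature_band, c("low", "high")])
    gain <- rep(1, n)
    for (o in config$seizure_onsets) {
      idx <- which(t >= o - config$signature_onset * 60 & t < o)
      if (length(idx))
        gain[idx] <- 1 + (config$effect_size - 1) *
          (t[idx] - (o - config$signature_onset * 60)) /
          (config$signature_onset * 60)
    }
    samples <- matrix(0, n, config$n_channels)
    nfft <- stats::nextn(n, factors = c(2, 3, 5))
    p_shape <- pink_shape(nfft, config$noise_exponent, fs)
    b_shape <- band_shape(nfft, band, fs)
    for (e in seq(1L, config$n_channels, by = 2L)) {
      pair <- e:min(e + 1L, config$n_channels)
      pink2 <- shaped_noise_pair(n, p_shape, nfft)
      band2 <- shaped_noise_pair(n, b_shape, nfft)
      for (j in seq_along(pair)) {
        lab <- config$channel_labels[pair[j]]
        x <- config$background_rms * pink2[, j] +
          config$alpha_amplitude *
            sin(2 * pi * 10 * t + stats::runif(1, 0, 2 * pi))
        b <- config$band_rms * band2[, j]
        if (lab %in% config$signature_electrodes) b <- b * gain
        x <- x + b
        if (config$ictal_burst) {
          for (o in config$seizure_onsets) {
            idx <- which(t >= o & t < o + 60)
            if (length(idx))
              x[idx] <- x[idx] + 100 * sin(2 * pi * 3 * t[idx])
          }
        }
        samples[, pair[j]] <- x
      }
    }
    truth <- structure(list(
      seizures = data.frame(
        onset_s = config$seizure_onsets,
        preictal_start_s = config$seizure_onsets - config$signature_onset * 60,
        ictal_end_s = pmin(config$seizure_onsets + 60, config$duration_s)),
      electrodes = config$signature_electrodes,
      band = config$signature_band,
      effect_size = config$effect_size),
      class = "ground_truth")
    list(recording = eeg_recording(samples, fs, config$channel_labels,
                                   onsets = config$seizure_onsets),
         truth = truth)
  })
}

# per-segment layout shared by generate_patient / simulate_patient
patient_plan <- function(config, n_train_seizures, n_test_seizures,
                         train_hours = 4,
                         test_lead_in_s = 7200, test_gap_s = 7200,
                         test_tail_s = 1800) {
  if (n_train_seizures < 2)
    stop("at least 2 training seizures are required (fitness needs one ",
         "train/test split)")
  if (n_test_seizures < 1) stop("at least 1 testing seizure is required")
  base_seed <- config$seed %||% 20260101L
  train <- lapply(seq_len(n_train_seizures), function(i) {
    cfg <- config
    cfg$duration_s <- train_hours * 3600
    cfg$seizure_onsets <- train_hours * 3600
    cfg$seed <- base_seed + i
    cfg
  })
  test_cfg <- config
  test_cfg$seizure_onsets <- test_lead_in_s +
    (seq_len(n_test_seizures) - 1) * test_gap_s
  test_cfg$duration_s <- max(test_cfg$seizure_onsets) + test_tail_s
  test_cfg$seed <- base_seed + n_train_seizures + 1L
  if (test_lead_in_s < config$signature_onset * 60 ||
      (n_test_seizures > 1 && test_gap_s <= config$signature_onset * 60 + 60))
    stop("test layout leaves overlapping or unplaceable pre-ictal windows")
  list(train = train, test = test_cfg)
}

#' Generate a synthetic patient dataset in memory
#'
#' Per-seizure training segments covering the last `train_hours` hours
#' before each training seizure (onset at the segment end) and one
#' continuous testing stretch containing all testing seizures.
#'
#' @inheritParams generate_patient
#' @return list with `train` (list of `generate_recording()` outputs, in
#'   chronological order), `test` (one `generate_recording()` output) and
#'   `config`.
#' @export
simulate_patient <- function(config, n_train_seizures, n_test_seizures,
                             train_hours = 4, test_lead_in_s = 7200,
                             test_gap_s = 7200, test_tail_s = 1800) {
  plan <- patient_plan(config, n_train_seizures, n_test_seizures,
                       train_hours, test_lead_in_s, test_gap_s, test_tail_s)
  list(train = lapply(plan$train, generate_recording),
       test = generate_recording(plan$test),
       config = config)
}

#' Generate a synthetic patient dataset on disk
#'
#' Writes `train_01.<ext>` ... (one 4-h segment per training seizure, in
#' chronological order), `test.<ext>` (one continuous record with all
#' testing onsets), per-file annotation sidecars, a combined
#' `annotations.csv` (columns `segment_id`, `onset_s`) and a
#' `ground_truth.csv` describing the planted signature (synthetic data, so
#' the truth is known).
#'
#' @param config a [synth_config()]; its seed drives all segments.
#' @param n_train_seizures number of training seizures (>= 2).
#' @param n_test_seizures number of testing seizures (>= 1).
#' @param dir output directory (created if needed).
#' @param format `"edf"` (16-bit EDF) or `"csv"`.
#' @param train_hours training segment length in hours (default 4).
#' @param test_lead_in_s,test_gap_s,test_tail_s layout of the continuous
#'   testing stretch in seconds.
#' @return manifest list with file paths and the annotation table,
#'   invisibly.
#' @export
generate_patient <- function(config, n_train_seizures, n_test_seizures,
                             dir, format = c("edf", "csv"),
                             train_hours = 4, test_lead_in_s = 7200,
                             test_gap_s = 7200, test_tail_s = 1800) {
  format <- match.arg(format)
  plan <- patient_plan(config, n_train_seizures, n_test_seizures,
                       train_hours, test_lead_in_s, test_gap_s, test_tail_s)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- paste0(".", format)
  paths <- character(0)
  ann <- data.frame(segment_id = character(0), onset_s = numeric(0))
  truth_rows <- list()
  for (i in seq_along(plan$train)) {
    seg_id <- sprintf("train_%02d", i)
    out <- generate_recording(plan$train[[i]])
    p <- file.path(dir, paste0(seg_id, ext))
    write_recording(out$recording, p)
    paths <- c(paths, p)
    ann <- rbind(ann, data.frame(segment_id = seg_id,
                                 onset_s = out$recording$onsets))
    truth_rows[[seg_id]] <- cbind(segment_id = seg_id, out$truth$seizures)
  }
  out <- generate_recording(plan$test)
  p <- file.path(dir, paste0("test", ext))
  write_recording(out$recording, p)
  paths <- c(paths, p)
  ann <- rbind(ann, data.frame(segment_id = "test",
                               onset_s = out$recording$onsets))
  truth_rows[["test"]] <- cbind(segment_id = "test", out$truth$seizures)
  utils::write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE)
  truth <- do.call(rbind, truth_rows)
  truth$electrodes <- paste(config$signature_electrodes, collapse = ";")
  truth$band <- config$signature_band
  truth$effect_size <- config$effect_size
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(list(dir = dir, files = paths, annotations = ann, truth = truth))
}
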