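# Recording container, filtering and 5-s segmentation.

#' Construct a multichannel EEG recording
#'
#' @param samples numeric matrix, time x channels, in microvolts.
#' @param sampling_rate sampling rate in Hz; must exceed twice the highest
#'   analysis frequency (90 Hz).
#' @param channel_labels one label per column (defaults to column names).
#' @param onsets seizure-onset annotations in seconds from record start,
#'   strictly increasing; may be empty (a "no seizures" recording).
#' @return an `eeg_recording` object.
#' @export
eeg_recording <- function(samples, sampling_rate,
                          channel_labels = colnames(samples),
                          onsets = numeric(0)) {
  samples <- as.matrix(samples)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(ncol(samples)))
  stopifnot(length(channel_labels) == ncol(samples))
  if (sampling_rate <= 2 * 90)
    stop("sampling_rate must exceed twice the highest analysis frequency (90 Hz)")
  onsets <- as.numeric(onsets)
  if (length(onsets) > 1L && any(diff(onsets) <= 0))
    stop("seizure onsets must be strictly increasing")
  dur <- nrow(samples) / sampling_rate
  if (length(onsets) && any(onsets < 0 | onsets > dur))
    stop("seizure onsets must lie within the record")
  colnames(samples) <- channel_labels
  structure(list(samples = samples,
                 sampling_rate = sampling_rate,
                 channel_labels = channel_labels,
                 onsets = onsets),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", ncol(x$samples), " channels x ",
      nrow(x$samples) / x$sampling_rate, " s @ ", x$sampling_rate, " Hz; ",
      if (length(x$onsets)) paste(length(x$onsets), "seizure onset(s)")
      else "no seizures", "\n", sep = "")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @export
recording_duration <- function(rec) nrow(rec$samples) / rec$sampling_rate

# RBJ biquad notch coefficients (b, a) for centre frequency f0 and quality Q
notch_coefficients <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1L], a = a / a[1L])
}

# squared magnitude response of an IIR filter interpolated onto arbitrary
# frequencies (Hz); the square is what a zero-phase forward-backward pass
# of the same filter applies
iir_power_gain <- function(b, a, freq_hz, fs, n_grid = 16384L) {
  w <- seq(0, pi, length.out = n_grid)
  h <- signal::freqz(b, a, region = NULL, n = w)$h
  g <- Mod(h)^2
  stats::approx(w * fs / (2 * pi), g, xout = freq_hz, rule = 2)$y
}

#' Notch and band-pass filter a recording
#'
#' Applies a 50 Hz notch (2nd-order IIR, Q = 30) and a 0.1-120 Hz
#' Butterworth band-pass (10th order), both zero-phase: the combined
#' squared magnitude response of the two filters (what a forward-backward
#' pass applies) is imposed in the frequency domain with reflection
#' padding, so window boundaries are not phase-shifted and hours-long
#' records filter in seconds. Output length equals input length.
#'
#' @param rec an `eeg_recording`.
#' @param notch_hz notch centre frequency (Hz).
#' @param band band-pass edges in Hz, `c(low, high)`.
#' @param notch_q notch quality factor.
#' @param bp_order Butterworth band-pass order (poles per skirt; the
#'   default 5 yields a 10th-order band-pass).
#' @return the filtered `eeg_recording`.
#' @export
filter_recording <- function(rec, notch_hz = 50, band = c(0.1, 120),
                             notch_q = 30, bp_order = 5L) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  nc <- notch_coefficients(notch_hz, fs, notch_q)
  bp <- signal::butter(bp_order, band / (fs / 2), type = "pass")
  gain_fn <- function(f)
    iir_power_gain(nc$b, nc$a, f, fs) * iir_power_gain(bp$b, bp$a, f, fs)
  out <- rec$samples
  n <- nrow(out)
  p <- min(n - 1L, as.integer(30 * fs))
  np <- stats::nextn(n + 2L * p, factors = c(2, 3, 5))
  f <- (seq_len(np) - 1L) * fs / np
  gain <- gain_fn(pmin(f, fs - f))
  pad <- function(x) {
    xp <- c(rev(x[seq_len(p)]), x, rev(x[(n - p + 1L):n]))
    c(xp, numeric(np - length(xp)))
  }
  # the gain is real and symmetric, so one complex FFT filters two
  # real channels at once (real part and imaginary part independently)
  for (e in seq(1L, ncol(out), by = 2L)) {
    z <- if (e < ncol(out))
      complex(real = pad(out[, e]), imaginary = pad(out[, e + 1L]))
    else pad(out[, e])
    y <- stats::fft(stats::fft(z) * gain, inverse = TRUE) / np
    out[, e] <- Re(y)[(p + 1L):(p + n)]
    if (e < ncol(out)) out[, e + 1L] <- Im(y)[(p + 1L):(p + n)]
  }
  rec$samples <- out
  rec
}

#' Segment a recording into non-overlapping 5-s analysis windows
#'
#' Windows are contiguous and timestamped by their start; the convention is
#' half-open `[start, start + window_s)` seconds with 0-based start times.
#' A trailing remainder shorter than one window is dropped.
#'
#' @param rec an `eeg_recording`.
#' @param window_s window length in seconds (default 5).
#' @return a `windowed_recording` with `n_windows`, `window_start_times`,
#'   `samples_per_window` and the sample matrix.
#' @export
segment_recording <- function(rec, window_s = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  spw <- as.integer(round(window_s * rec$sampling_rate))
  n <- nrow(rec$samples)
  if (n < spw) stop("record shorter than one analysis window")
  n_windows <- n %/% spw
  structure(list(samples = rec$samples,
                 sampling_rate = rec$sampling_rate,
                 channel_labels = rec$channel_labels,
                 onsets = rec$onsets,
                 window_s = window_s,
                 samples_per_window = spw,
                 n_windows = n_windows,
                 window_start_times = (seq_len(n_windows) - 1) * window_s),
            class = "windowed_recording")
}

#' Extract one analysis window from a segmented recording
#'
#' @param windowed a `windowed_recording`.
#' @param k window index (1-based).
#' @param channel channel label or index.
#' @return numeric vector of `samples_per_window` samples.
#' @export
get_window <- function(windowed, k, channel) {
  stopifnot(inherits(windowed, "windowed_recording"),
            k >= 1L, k <= windowed$n_windows)
  spw <- windowed$samples_per_window
  idx <- ((k - 1L) * spw + 1L):(k * spw)
  windowed$samples[idx, channel]
}

#' @export
print.windowed_recording <- function(x, ...) {
  cat("<windowed_recording> ", x$n_windows, " windows of ", x$window_s,
      " s x ", length(x$channel_labels), " channels\n", sep = "")
  invisible(x)
}
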