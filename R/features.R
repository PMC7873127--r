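# First-level feature extraction: 12 features per 5-s window per electrode.

#' Spectral analysis bands
#'
#' Seven disjoint, ordered bands spanning 0.5-90 Hz; gamma is split in three
#' sub-bands because its upper limit is not consensual in the field.
#'
#' @return data.frame with columns `name`, `low`, `high` (Hz).
#' @export
band_definitions <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma1", "gamma2", "gamma3"),
    low  = c(0.5, 4, 8, 13, 36, 51, 71),
    high = c(3.5, 7.5, 12, 35, 50, 70, 90),
    stringsAsFactors = FALSE)
}

#' Canonical order of the 12 first-level features
#'
#' Seven relative band powers followed by the five non-band-wave features.
#' `mean_amplitude` is the mean absolute amplitude of the window (also
#' known as medium temporal intensity); `normalized_mean_amplitude` divides
#' it by the window's maximum absolute value.
#'
#' @return character vector of length 12.
#' @export
feature_names <- function() {
  c(paste0("rel_power_", band_definitions()$name),
    "average_power", "mean_normalized_frequency",
    "normalized_mean_amplitude", "mean_amplitude", "amplitude_variance")
}

#' Names of the non-band-wave feature group
#' @return character vector of length 5.
#' @export
non_band_features <- function() feature_names()[8:12]

#' Names of the band-wave feature group (the 7 relative powers)
#' @return character vector of length 7.
#' @export
band_features <- function() feature_names()[1:7]

# frequency-bin membership masks over the welch grid; the relative-power
# denominator is total power over 0.5-90 Hz (the union span of the bands)
band_masks <- function(freq) {
  bd <- band_definitions()
  masks <- lapply(seq_len(nrow(bd)),
                  function(i) freq >= bd$low[i] & freq <= bd$high[i])
  names(masks) <- bd$name
  masks$total <- freq >= 0.5 & freq <= 90
  masks
}

spectral_features_from_psd <- function(freq, psd) {
  # psd: freq x windows matrix; returns 9 x windows matrix
  masks <- band_masks(freq)
  tot <- colSums(psd[masks$total, , drop = FALSE])
  out <- matrix(0, 9L, ncol(psd))
  degen <- tot <= 0
  safe_tot <- ifelse(degen, 1, tot)
  for (i in 1:7) {
    out[i, ] <- colSums(psd[masks[[i]], , drop = FALSE]) / safe_tot
  }
  out[8, ] <- colMeans(psd[masks$total, , drop = FALSE])
  f_tot <- freq[masks$total]
  out[9, ] <- colSums(psd[masks$total, , drop = FALSE] * f_tot) / safe_tot
  out[, degen] <- 0
  attr(out, "degenerate") <- degen
  out
}

#' Relative power in the seven analysis bands
#'
#' Each value is the Welch-estimated power in the band divided by the total
#' power over 0.5-90 Hz; values lie in `[0, 1]` and the seven of them sum to
#' at most 1. An all-zero (degenerate) window returns zeros and carries a
#' `degenerate` attribute.
#'
#' @param x single-channel window (numeric vector).
#' @param fs sampling rate in Hz.
#' @return named numeric vector of length 7.
#' @export
band_relative_powers <- function(x, fs) {
  w <- welch_psd(x, fs)
  sf <- spectral_features_from_psd(w$freq, matrix(w$psd, ncol = 1L))
  out <- sf[1:7, 1L]
  names(out) <- paste0("rel_power_", band_definitions()$name)
  attr(out, "degenerate") <- attr(sf, "degenerate")[1L]
  out
}

#' Average power and mean normalized frequency of a window
#'
#' Average power is the mean PSD over 0.5-90 Hz; mean normalized frequency
#' is the spectral centroid (Hz) of the PSD normalized to unit area over the
#' same span.
#'
#' @inheritParams band_relative_powers
#' @return named numeric vector `c(average_power, mean_normalized_frequency)`.
#' @export
spectral_summaries <- function(x, fs) {
  w <- welch_psd(x, fs)
  sf <- spectral_features_from_psd(w$freq, matrix(w$psd, ncol = 1L))
  out <- c(average_power = sf[8, 1L], mean_normalized_frequency = sf[9, 1L])
  attr(out, "degenerate") <- attr(sf, "degenerate")[1L]
  out
}

#' Amplitude statistics of a window
#'
#' Mean absolute amplitude, the same normalized by the window's maximum
#' absolute value, and the amplitude variance. A flat zero window returns
#' zeros with a `degenerate` attribute.
#'
#' @param x single-channel window (numeric vector).
#' @return named numeric vector
#'   `c(normalized_mean_amplitude, mean_amplitude, amplitude_variance)`.
#' @export
amplitude_stats <- function(x) {
  m <- mean(abs(x))
  mx <- max(abs(x))
  degen <- mx == 0
  out <- c(normalized_mean_amplitude = if (degen) 0 else m / mx,
           mean_amplitude = m,
           amplitude_variance = stats::var(x))
  attr(out, "degenerate") <- degen
  out
}

#' Extract the 12 first-level features for every window and electrode
#'
#' @param windowed a `windowed_recording` from [segment_recording()].
#' @return a `feature_tensor`: list with `values` (array
#'   `windows x electrodes x 12`), `feature_names`, `window_start_times`
#'   (s), `sampling_rate`, `electrodes`, and a logical `degenerate`
#'   matrix (`windows x electrodes`).
#' @export
extract_features <- function(windowed) {
  stopifnot(inherits(windowed, "windowed_recording"))
  W <- windowed$n_windows
  labs <- windowed$channel_labels
  E <- length(labs)
  fs <- windowed$sampling_rate
  spw <- windowed$samples_per_window
  fn <- feature_names()
  values <- array(NA_real_, dim = c(W, E, 12L),
                  dimnames = list(NULL, labs, fn))
  degen <- matrix(FALSE, W, E, dimnames = list(NULL, labs))
  n_used <- W * spw
  for (e in seq_len(E)) {
    xm <- matrix(windowed$samples[seq_len(n_used), e], nrow = spw)
    w <- welch_psd(xm, fs)
    sf <- spectral_features_from_psd(w$freq, w$psd)
    values[, e, 1:9] <- t(sf)
    absx <- abs(xm)
    m <- colMeans(absx)
    mx <- apply(absx, 2L, max)
    mu <- colMeans(xm)
    v <- (colSums(xm^2) - spw * mu^2) / (spw - 1)
    values[, e, 10L] <- ifelse(mx == 0, 0, m / mx)
    values[, e, 11L] <- m
    values[, e, 12L] <- pmax(v, 0)
    degen[, e] <- attr(sf, "degenerate") | mx == 0
  }
  structure(list(values = values,
                 feature_names = fn,
                 window_start_times = windowed$window_start_times,
                 window_s = windowed$window_s,
                 sampling_rate = fs,
                 electrodes = labs,
                 degenerate = degen),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat("<feature_tensor> ", dim(x$values)[1L], " windows x ",
      dim(x$values)[2L], " electrodes x 12 features (",
      x$window_s, "-s windows)\n", sep = "")
  invisible(x)
}

#' Write / read a feature tensor as a flat table
#'
#' Long CSV with columns `window_start_s`, `electrode`, `feature`, `value`.
#'
#' @param tensor a `feature_tensor`.
#' @param path CSV file path.
#' @return `write_feature_tensor` returns `path` invisibly;
#'   `read_feature_tensor` returns a `feature_tensor` (without degenerate
#'   flags, which are not persisted).
#' @export
write_feature_tensor <- function(tensor, path) {
  d <- dim(tensor$values)
  df <- data.frame(
    window_start_s = rep(tensor$window_start_times, times = d[2L] * d[3L]),
    electrode = rep(rep(tensor$electrodes, each = d[1L]), times = d[3L]),
    feature = rep(tensor$feature_names, each = d[1L] * d[2L]),
    value = as.vector(tensor$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tensor
#' @param sampling_rate sampling rate to record on the restored tensor.
#' @export
read_feature_tensor <- function(path, sampling_rate = 256) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  starts <- sort(unique(df$window_start_s))
  electrodes <- unique(df$electrode)
  fn <- feature_names()
  values <- array(NA_real_,
                  dim = c(length(starts), length(electrodes), length(fn)),
                  dimnames = list(NULL, electrodes, fn))
  wi <- match(df$window_start_s, starts)
  ei <- match(df$electrode, electrodes)
  fi <- match(df$feature, fn)
  values[cbind(wi, ei, fi)] <- df$value
  window_s <- if (length(starts) > 1L) diff(starts[1:2]) else 5
  structure(list(values = values, feature_names = fn,
                 window_start_times = starts, window_s = window_s,
                 sampling_rate = sampling_rate, electrodes = electrodes,
                 degenerate = matrix(FALSE, length(starts), length(electrodes))),
            class = "feature_tensor")
}
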