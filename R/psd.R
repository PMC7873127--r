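# Welch power spectral density estimation.
#
# No installed package exposes a Welch estimator, so it is implemented here:
# Hann-tapered segments, 50% overlap, one-sided density scaling. The batch
# path computes the PSD of many equal-length windows in one mvfft call, which
# is what makes whole-recording feature extraction affordable.

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
}

#' Welch PSD of one or many equal-length signal windows
#'
#' @param x numeric vector (one window) or a matrix with one window per
#'   column.
#' @param fs sampling rate in Hz.
#' @param seg_len segment length in samples (default `fs`, i.e. 1-s segments
#'   giving 1-Hz resolution).
#' @param overlap fractional segment overlap (default 0.5).
#' @return list with `freq` (Hz, 0..Nyquist) and `psd` (density in
#'   units^2/Hz; a vector for vector input, a matrix `freq x windows` for
#'   matrix input).
#' @export
welch_psd <- function(x, fs, seg_len = fs, overlap = 0.5) {
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  n <- nrow(xm)
  if (n < seg_len) stop("window shorter than one Welch segment")
  hop <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq.int(1L, n - seg_len + 1L, by = hop)
  nseg <- length(starts)
  win <- hann_window(seg_len)
  scale <- fs * sum(win^2)
  nf <- seg_len %/% 2L + 1L
  nw_total <- ncol(xm)
  psd <- matrix(0, nf, nw_total)
  # one segment-index template reused for every window in the chunk
  seg_idx <- as.vector(outer(seq_len(seg_len), starts - 1L, `+`))
  chunk <- max(1L, 4096L %/% nseg * nseg)  # bound memory of the fft matrix
  done <- 0L
  while (done < nw_total) {
    cols <- (done + 1L):min(nw_total, done + chunk %/% 1L)
    block <- xm[, cols, drop = FALSE]
    nb <- length(cols)
    idx <- rep.int(seg_idx, nb) + rep((seq_len(nb) - 1L) * n, each = length(seg_idx))
    S <- matrix(block[idx], nrow = seg_len) * win
    Fm <- stats::mvfft(S)
    P <- Mod(Fm[seq_len(nf), , drop = FALSE])^2 / scale
    if (nf > 2L) P[2:(nf - 1L), ] <- 2 * P[2:(nf - 1L), , drop = FALSE]
    dim(P) <- c(nf, nseg, nb)
    acc <- matrix(0, nf, nb)
    for (s in seq_len(nseg)) acc <- acc + P[, s, ]
    psd[, cols] <- acc / nseg
    done <- done + nb
  }
  freq <- (seq_len(nf) - 1L) * fs / seg_len
  if (is.matrix(x)) list(freq = freq, psd = psd)
  else list(freq = freq, psd = psd[, 1L])
}
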