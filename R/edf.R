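# Minimal 16-bit EDF (European Data Format) writer/reader.
#
# Covers the subset of EDF this package emits: continuous recording, one
# data record per second, all signals at the same sampling rate, physical
# units in microvolts. Signals are scaled per channel to the full 16-bit
# digital range.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with 1-s data records; each channel is scaled to the full
#' digital range, so the round-trip error is bounded by the per-channel
#' quantization step. Seizure annotations are not stored in the EDF itself;
#' use [write_annotations()] for the sidecar table.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- as.integer(round(rec$sampling_rate))
  n <- nrow(rec$samples)
  if (n %% fs != 0)
    stop("EDF export requires a whole number of 1-s data records")
  n_rec <- n %/% fs
  ns <- ncol(rec$samples)
  phys_max <- apply(abs(rec$samples), 2L, max)
  phys_max[phys_max == 0] <- 1
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  header_bytes <- 256L + 256L * ns
  wr(pad_field("0", 8))
  wr(pad_field("X X X X", 80))
  wr(pad_field("Startdate X synthetic", 80))
  wr(pad_field("01.01.00", 8))
  wr(pad_field("00.00.00", 8))
  wr(pad_field(header_bytes, 8))
  wr(pad_field("", 44))
  wr(pad_field(n_rec, 8))
  wr(pad_field("1", 8))
  wr(pad_field(ns, 4))
  for (lab in rec$channel_labels) wr(pad_field(paste("EEG", lab), 16))
  for (i in seq_len(ns)) wr(pad_field("AgAgCl electrode", 80))
  for (i in seq_len(ns)) wr(pad_field("uV", 8))
  for (i in seq_len(ns)) wr(pad_field(sprintf("%.6g", -phys_max[i]), 8))
  for (i in seq_len(ns)) wr(pad_field(sprintf("%.6g", phys_max[i]), 8))
  for (i in seq_len(ns)) wr(pad_field(-dig_max, 8))
  for (i in seq_len(ns)) wr(pad_field(dig_max, 8))
  for (i in seq_len(ns)) wr(pad_field("", 80))
  for (i in seq_len(ns)) wr(pad_field(fs, 8))
  for (i in seq_len(ns)) wr(pad_field("", 32))
  # digital conversion, channel-major inside each 1-s record
  scale <- dig_max / phys_max
  dig <- matrix(0L, n, ns)
  for (i in seq_len(ns)) {
    d <- as.integer(round(rec$samples[, i] * scale[i]))
    dig[, i] <- as.integer(pmax(pmin(d, dig_max), -dig_max))
  }
  out <- integer(n * ns)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    out[((r - 1L) * fs * ns + 1L):(r * fs * ns)] <- as.vector(dig[rows, ])
  }
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF file written by this package (or any same-rate 16-bit EDF)
#'
#' @param path EDF file path.
#' @return list with `samples` (time x channels, physical units),
#'   `sampling_rate`, `channel_labels`.
#' @export
read_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not an EDF file (truncated header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header: ", path)
  if (sz < 256L + 256L * ns) stop("not an EDF file (truncated header): ", path)
  field <- function(width) vapply(seq_len(ns), function(i) rd(width), character(1))
  labels <- sub("^EEG ", "", field(16))
  field(80)
  field(8)
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8))
  field(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1L] / rec_dur
  expected <- header_bytes + 2 * n_rec * sum(spr)
  if (sz < expected)
    stop("truncated EDF data section: ", path, " (expected ", expected,
         " bytes, found ", sz, ")")
  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2L,
                 endian = "little")
  samples <- matrix(0, n_rec * spr[1L], ns)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  off <- phys_max - gain * dig_max
  per_rec <- sum(spr)
  for (r in seq_len(n_rec)) {
    base <- (r - 1L) * per_rec
    rows <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    block <- matrix(raw[(base + 1L):(base + per_rec)], nrow = spr[1L])
    samples[rows, ] <- sweep(sweep(block, 2L, gain, `*`), 2L, off, `+`)
  }
  colnames(samples) <- labels
  list(samples = samples, sampling_rate = fs, channel_labels = labels)
}
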