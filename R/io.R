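# Recording I/O: EDF or CSV signal dialect plus a sidecar annotation table.

annotation_path_for <- function(path) {
  paste0(sub("\\.[^.]+$", "", path), ".ann.csv")
}

#' Write the seizure-annotation sidecar for a signal file
#'
#' @param onsets onset times in seconds.
#' @param path path of the annotation CSV (or of the signal file, in which
#'   case the conventional `<stem>.ann.csv` name is used).
#' @return the annotation path, invisibly.
#' @export
write_annotations <- function(onsets, path) {
  if (!grepl("\\.ann\\.csv$", path)) path <- annotation_path_for(path)
  utils::write.csv(data.frame(onset_s = as.numeric(onsets)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a recording (signals + annotation sidecar)
#'
#' The format is chosen by extension: `.edf` for 16-bit EDF, `.csv` for the
#' plain-text dialect (one column per channel, header = channel labels).
#' Seizure onsets go to the `<stem>.ann.csv` sidecar in both cases.
#'
#' @param rec an `eeg_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    write_edf(rec, path)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- as.data.frame(rec$samples)
    names(df) <- rec$channel_labels
    utils::write.csv(df, path, row.names = FALSE)
  } else stop("unsupported recording format: ", path)
  write_annotations(rec$onsets, path)
  invisible(path)
}

#' Read a recording from EDF or the CSV signal dialect
#'
#' The annotation sidecar `<stem>.ann.csv` must exist (it may list zero
#' onsets, flagging a "no seizures" record). Unknown channel labels are
#' preserved verbatim. There is no silent resampling: if `expected_rate` is
#' given and the file's rate differs, reading fails.
#'
#' @param path signal file (`.edf` or `.csv`).
#' @param sampling_rate sampling rate for CSV input (EDF carries its own).
#' @param expected_rate if non-`NULL`, the rate the caller requires.
#' @param annotation_path optional explicit sidecar path.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, sampling_rate = 256, expected_rate = NULL,
                           annotation_path = NULL) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  ann_path <- annotation_path %||% annotation_path_for(path)
  if (!file.exists(ann_path))
    stop("missing annotation table: ", ann_path)
  ann <- utils::read.csv(ann_path)
  if (!"onset_s" %in% names(ann))
    stop("annotation table must have an onset_s column: ", ann_path)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    raw <- read_edf(path)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, check.names = FALSE)
    raw <- list(samples = as.matrix(df), sampling_rate = sampling_rate,
                channel_labels = names(df))
  } else stop("unsupported recording format: ", path)
  if (!is.null(expected_rate) && raw$sampling_rate != expected_rate)
    stop("sampling rate mismatch: file has ", raw$sampling_rate,
         " Hz, expected ", expected_rate, " Hz (no silent resampling)")
  eeg_recording(raw$samples, raw$sampling_rate, raw$channel_labels,
                onsets = ann$onset_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
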