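# Firing Power regularization and alarm generation.

#' Firing Power: trailing moving average of binary classifier outputs
#'
#' Quantifies the rate of pre-ictal classifications over a trailing window
#' whose length equals the pre-ictal period (in 1-min samples). During
#' warm-up, before the window has filled, the mean over the available
#' samples is emitted so continuous evaluation is defined from the first
#' sample.
#'
#' @param outputs binary (0/1) classifier outputs on the 1-min grid.
#' @param window_min window length in minutes (the pre-ictal duration).
#' @return numeric vector in `[0, 1]`, same length as `outputs`.
#' @export
firing_power <- function(outputs, window_min) {
  stopifnot(window_min >= 1)
  outputs <- as.numeric(outputs)
  n <- length(outputs)
  w <- as.integer(round(window_min))
  cs <- c(0, cumsum(outputs))
  k <- seq_len(n)
  lo <- pmax(k - w, 0L)
  (cs[k + 1L] - cs[lo + 1L]) / (k - lo)
}

#' Raise alarms at upward threshold crossings of the Firing Power
#'
#' An alarm fires at the first sample where the Firing Power exceeds the
#' threshold after having been at or below it (the first sample itself can
#' fire). In testing mode a refractory period follows each alarm: crossings
#' within `refractory_min` minutes of the previous alarm are suppressed and
#' the suppressed interval is recorded.
#'
#' @param fp Firing Power series in `[0, 1]`.
#' @param times sample times in seconds (1-min grid).
#' @param threshold alarm threshold (default 0.70).
#' @param refractory_min refractory period in minutes (`NULL` = none; the
#'   testing stage uses SOP + SPH).
#' @return an `alarm_train`: list with `times` (alarm times, s),
#'   `fp`, `grid`, `threshold`, `refractory_min` and a 2-column
#'   `refractory` matrix of suppressed intervals (s).
#' @export
trigger_alarms <- function(fp, times, threshold = 0.70,
                           refractory_min = NULL) {
  stopifnot(length(fp) == length(times))
  above <- fp > threshold
  crossing <- above & !c(FALSE, above[-length(above)])
  alarm_times <- numeric(0)
  refr <- NULL
  if (is.null(refractory_min)) {
    alarm_times <- times[crossing]
  } else {
    refr_s <- refractory_min * 60
    last <- -Inf
    for (k in which(crossing)) {
      if (times[k] < last + refr_s) next
      alarm_times <- c(alarm_times, times[k])
      last <- times[k]
    }
    refr <- cbind(start = alarm_times, end = alarm_times + refr_s)
  }
  structure(list(times = alarm_times, fp = fp, grid = times,
                 threshold = threshold, refractory_min = refractory_min,
                 refractory = refr),
            class = "alarm_train")
}

#' @export
print.alarm_train <- function(x, ...) {
  cat("<alarm_train>", length(x$times), "alarm(s) at threshold",
      x$threshold,
      if (!is.null(x$refractory_min))
        paste0("(refractory ", x$refractory_min, " min)") else "", "\n")
  invisible(x)
}
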