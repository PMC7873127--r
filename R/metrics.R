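# Seizure-prediction performance metrics and the composite score.

#' Composite seizure-prediction performance
#'
#' `performance = (S_s + S_p) * 0.5 - FPR/h * (1 + T_f)`. The optimum is 1:
#' all pre-ictal samples classified correctly (`S_s = 1`), the seizure
#' predicted (`S_p = 1`), no inter-ictal sample misclassified (`T_f = 0`)
#' and no false alarm (`FPR/h = 0`). FPR/h is weighted by `1 + T_f` so a
#' given time under false alarm is penalized more when it is spread over
#' many alarms.
#'
#' @param s_s sample sensitivity in `[0, 1]`.
#' @param s_p seizure sensitivity in `[0, 1]`.
#' @param fpr_h false alarms per inter-ictal hour.
#' @param t_f time under false alarm in `[0, 1]`.
#' @return the composite performance (<= 1).
#' @export
performance_score <- function(s_s, s_p, fpr_h, t_f) {
  (s_s + s_p) * 0.5 - fpr_h * (1 + t_f)
}

#' Evaluate a fitted model on one hyper-feature series
#'
#' Sample-level metrics use the raw classifier decisions (`p > 0.5`):
#' `S_s` is the fraction of pre-ictal rows classified pre-ictal and `T_f`
#' the fraction of inter-ictal rows classified pre-ictal. Alarm-level
#' metrics use the Firing Power (threshold 0.70, window = pre-ictal
#' period): `S_p` is 1 for a seizure with at least one alarm inside
#' `[onset - pre-ictal, onset - SPH)`, and FPR/h counts alarms raised on
#' inter-ictal rows per inter-ictal hour. In testing mode alarms carry an
#' SOP+SPH refractory period, which is also removed from the FPR/h
#' denominator (only time during which a false alarm could fire counts).
#'
#' @param series a lag-expanded `hf_series` (see [add_lags()]).
#' @param model an `hf_model`.
#' @param mode `"fitness"` (no refractory) or `"test"`.
#' @param fp_threshold Firing Power alarm threshold (default 0.70).
#' @return a `perf_metrics` list: `s_s`, `s_p`, `t_f`, `fpr_h`,
#'   `performance`, per-seizure prediction flags, the `alarm_train` and the
#'   false-alarm count.
#' @export
evaluate_seizure <- function(series, model, mode = c("fitness", "test"),
                             fp_threshold = 0.70) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "hf_series"))
  p <- predict_probability(model, series$X)
  binary <- as.numeric(p > 0.5)
  pre <- series$labels == "preictal"
  inter <- series$labels == "interictal"
  if (!any(inter)) stop("series has no inter-ictal rows")
  if (!any(pre)) stop("series has no pre-ictal rows")
  s_s <- mean(binary[pre])
  t_f <- mean(binary[inter])
  fp <- firing_power(binary, series$pre_ictal_min)
  refractory <- if (mode == "test") series$sop_min + series$sph_min else NULL
  alarms <- trigger_alarms(fp, series$times, threshold = fp_threshold,
                           refractory_min = refractory)
  predicted <- vapply(series$onsets, function(o)
    any(alarms$times >= o - series$pre_ictal_min * 60 &
          alarms$times < o - series$sph_min * 60), logical(1))
  s_p <- if (length(predicted)) mean(predicted) else 0
  alarm_labels <- series$labels[match(alarms$times, series$times)]
  n_false <- sum(alarm_labels == "interictal")
  inter_min <- sum(inter)
  if (mode == "test" && !is.null(alarms$refractory) &&
      nrow(alarms$refractory)) {
    in_refr <- rep(FALSE, length(series$times))
    for (r in seq_len(nrow(alarms$refractory)))
      in_refr <- in_refr |
        (series$times > alarms$refractory[r, 1L] &
           series$times <= alarms$refractory[r, 2L])
    inter_min <- sum(inter & !in_refr)
  }
  if (inter_min <= 0) stop("no inter-ictal time left for FPR/h")
  fpr_h <- n_false / (inter_min / 60)
  structure(list(s_s = s_s, s_p = s_p, t_f = t_f, fpr_h = fpr_h,
                 performance = performance_score(s_s, s_p, fpr_h, t_f),
                 per_seizure = predicted, alarms = alarms,
                 n_false = n_false, inter_hours = inter_min / 60),
            class = "perf_metrics")
}

#' @export
print.perf_metrics <- function(x, ...) {
  cat(sprintf(
    "<perf_metrics> Ss %.3f | Sp %.3f | Tf %.3f | FPR/h %.3f | performance %.3f\n",
    x$s_s, x$s_p, x$t_f, x$fpr_h, x$performance))
  invisible(x)
}
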