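# Statistical validation: surrogate predictor by seizure-time shifting,
# one-tailed t-test against it, and the binomial execution-count test.

#' Surrogate seizure sensitivity by random seizure-time shifting
#'
#' Monte Carlo chance-level baseline: the alarm train computed once on the
#' real data is kept fixed while seizure onset times are displaced
#' uniformly at random (each shifted pre-ictal window must fit inside the
#' record; draws whose windows would overlap each other are resampled with
#' capped retries). Surrogate sensitivity per repetition is the fraction
#' of shifted onsets with at least one alarm inside their pre-ictal window.
#'
#' @param alarm_times alarm times (s) from the real test evaluation.
#' @param onsets real onset times (only their count matters).
#' @param duration_s record length in seconds.
#' @param pre_ictal_min pre-ictal period (minutes).
#' @param sph_min seizure prediction horizon (minutes, default 10).
#' @param n_reps Monte Carlo repetitions (default 30).
#' @param seed optional seed.
#' @param max_retries resampling cap per repetition.
#' @return a `surrogate_result`: `sensitivities` (length `n_reps`),
#'   `mean`, `sd`, `n_reps`.
#' @export
surrogate_sensitivity <- function(alarm_times, onsets, duration_s,
                                  pre_ictal_min, sph_min = 10,
                                  n_reps = 30L, seed = NULL,
                                  max_retries = 100L) {
  stopifnot(length(onsets) >= 1L, duration_s > pre_ictal_min * 60)
  with_seed(seed, {
    lo <- pre_ictal_min * 60
    hi <- duration_s
    sens <- vapply(seq_len(n_reps), function(rep) {
      for (try in seq_len(max_retries)) {
        shifted <- sort(stats::runif(length(onsets), lo, hi))
        if (length(shifted) < 2L ||
            all(diff(shifted) >= pre_ictal_min * 60)) {
          hit <- vapply(shifted, function(o)
            any(alarm_times >= o - pre_ictal_min * 60 &
                  alarm_times < o - sph_min * 60), logical(1))
          return(mean(hit))
        }
      }
      stop("record too short to place non-overlapping shifted pre-ictal ",
           "windows")
    }, numeric(1))
    structure(list(sensitivities = sens, mean = mean(sens),
                   sd = stats::sd(sens), n_reps = n_reps),
              class = "surrogate_result")
  })
}

#' @export
print.surrogate_result <- function(x, ...) {
  cat(sprintf("<surrogate_result> %.3f +/- %.3f over %d repetitions\n",
              x$mean, x$sd, x$n_reps))
  invisible(x)
}

#' One-tailed test of real sensitivity against the surrogate predictor
#'
#' Welch (unequal-variance) two-sample t-test of the one-sided alternative
#' that the real sensitivities exceed the surrogate ones; the execution is
#' flagged "above chance" when p < alpha and the real mean is larger. When
#' both groups have zero variance the test degenerates to an exact
#' comparison of means (p of 0 or 1).
#'
#' @param real_sensitivities per-seizure (or per-execution) sensitivities.
#' @param surrogate a `surrogate_result` or a numeric vector of surrogate
#'   sensitivities.
#' @param alpha significance level (default 0.01).
#' @return list with `flag`, `p_value`, `t`, means of both groups.
#' @export
above_chance_test <- function(real_sensitivities, surrogate, alpha = 0.01) {
  surr <- if (inherits(surrogate, "surrogate_result"))
    surrogate$sensitivities else as.numeric(surrogate)
  stopifnot(length(real_sensitivities) >= 2L, length(surr) >= 2L)
  m_real <- mean(real_sensitivities)
  m_surr <- mean(surr)
  if (stats::sd(real_sensitivities) == 0 && stats::sd(surr) == 0) {
    p <- if (m_real > m_surr) 0 else 1
    t_stat <- NA_real_
  } else {
    ht <- stats::t.test(real_sensitivities, surr, alternative = "greater",
                        var.equal = FALSE)
    p <- ht$p.value
    t_stat <- unname(ht$statistic)
  }
  list(flag = (p < alpha) && (m_real > m_surr), p_value = p, t = t_stat,
       mean_real = m_real, mean_surrogate = m_surr, alpha = alpha)
}

#' Binomial tail probability of the execution count
#'
#' Probability of observing at least `i` of `I` executions above chance
#' when each flags independently with probability `alpha`:
#' `P = sum_{j=i}^{I} C(I,j) alpha^j (1-alpha)^(I-j)`.
#'
#' @param i observed count (0..I).
#' @param I number of executions.
#' @param alpha per-execution null probability.
#' @return the tail probability.
#' @export
binomial_prob <- function(i, I, alpha) {
  if (length(i) != 1L || length(I) != 1L || i < 0 || I < 1 || i > I ||
      alpha < 0 || alpha > 1)
    stop("invalid binomial arguments: need 0 <= i <= I, 0 <= alpha <= 1")
  j <- seq.int(i, I)
  sum(choose(I, j) * alpha^j * (1 - alpha)^(I - j))
}

#' Patient-level statistical validation over a set of executions
#'
#' Runs the per-execution above-chance test (alpha 0.01), an overall test
#' pooling per-execution mean sensitivities against per-execution surrogate
#' means, and the binomial test of whether the flagged count is itself
#' significant for the whole set (per-execution null probability 0.05).
#'
#' @param real_sensitivities list (one element per execution) of
#'   per-seizure sensitivity vectors.
#' @param surrogates list of matching `surrogate_result`s.
#' @param alpha_execution per-execution significance level (default 0.01).
#' @param alpha_binomial per-execution null probability and significance
#'   level of the binomial count test (default 0.05).
#' @return a `validation_report`: per-execution flags and p-values, the
#'   flagged ratio, the overall above-chance flag, and the binomial
#'   p-value with its significance flag.
#' @export
validate_patient <- function(real_sensitivities, surrogates,
                             alpha_execution = 0.01,
                             alpha_binomial = 0.05) {
  stopifnot(length(real_sensitivities) == length(surrogates))
  n_exec <- length(real_sensitivities)
  tests <- lapply(seq_len(n_exec), function(i)
    above_chance_test(real_sensitivities[[i]], surrogates[[i]],
                      alpha = alpha_execution))
  flags <- vapply(tests, `[[`, logical(1), "flag")
  exec_means <- vapply(real_sensitivities, mean, numeric(1))
  surr_means <- vapply(surrogates, function(s)
    if (inherits(s, "surrogate_result")) s$mean else mean(s), numeric(1))
  overall <- above_chance_test(exec_means, surr_means,
                               alpha = alpha_execution)
  p_binom <- binomial_prob(sum(flags), n_exec, alpha_binomial)
  structure(list(per_execution = tests,
                 flags = flags,
                 ratio_above_chance = mean(flags),
                 overall = overall,
                 binomial_p = p_binom,
                 binomial_significant = p_binom < alpha_binomial,
                 n_executions = n_exec),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %d/%d execution(s) above chance (ratio %.2f)\n",
    sum(x$flags), x$n_executions, x$ratio_above_chance))
  cat(sprintf("  overall above chance: %s (p = %.4g)\n",
              x$overall$flag, x$overall$p_value))
  cat(sprintf("  binomial count test: p = %.4g (%ssignificant)\n",
              x$binomial_p, if (x$binomial_significant) "" else "not "))
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report a `validation_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  obj <- list(
    flags = report$flags,
    ratio_above_chance = report$ratio_above_chance,
    per_execution_p = vapply(report$per_execution, `[[`, numeric(1),
                             "p_value"),
    overall = report$overall[c("flag", "p_value", "mean_real",
                               "mean_surrogate")],
    binomial_p = report$binomial_p,
    binomial_significant = report$binomial_significant)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
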