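# Redundancy filtering, standardization and the class-weighted logistic
# regression at the heart of the fitness function.

#' Greedy correlation filter
#'
#' Scans columns left to right; a column is dropped iff its absolute
#' Pearson correlation with any already-retained column exceeds the
#' threshold. Zero-variance columns (correlation undefined) are dropped
#' with a warning.
#'
#' @param X numeric matrix (rows = samples).
#' @param threshold absolute-correlation threshold (default 0.95).
#' @return integer vector of retained column indices.
#' @export
correlation_filter <- function(X, threshold = 0.95) {
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  sds <- apply(X, 2L, stats::sd)
  degenerate <- !is.finite(sds) | sds == 0
  if (any(degenerate))
    warning("dropping ", sum(degenerate),
            " zero-variance column(s): correlation undefined")
  retained <- integer(0)
  for (j in seq_len(ncol(X))) {
    if (degenerate[j]) next
    if (length(retained)) {
      rho <- suppressWarnings(stats::cor(X[, j], X[, retained, drop = FALSE]))
      if (any(abs(rho) > threshold, na.rm = TRUE)) next
    }
    retained <- c(retained, j)
  }
  retained
}

#' Fit the class-weighted logistic regression of the prediction pipeline
#'
#' Applies the correlation filter, z-scores the retained columns (training
#' statistics only), weights each class inversely to its frequency
#' (`w_c = N / (2 N_c)`) and fits a binomial GLM. The stored z-score
#' parameters and retained-column list are reused verbatim at test time, so
#' no test statistics ever leak into the model.
#'
#' @param X design matrix (lag-expanded hyper-feature columns).
#' @param labels character vector with values `preictal` / `interictal`
#'   (rows labelled otherwise must be removed beforehand).
#' @param cor_threshold correlation-filter threshold.
#' @return an `hf_model`: intercept `beta0`, coefficients `beta` (one per
#'   retained column), z-score `center`/`scale`, `retained` column names.
#' @export
fit_classifier <- function(X, labels, cor_threshold = 0.95) {
  stopifnot(is.matrix(X), nrow(X) == length(labels))
  y <- labels == "preictal"
  if (all(y) || !any(y))
    stop("training data contains a single class")
  keep <- correlation_filter(X, cor_threshold)
  if (!length(keep)) stop("no columns survive the correlation filter")
  Xr <- X[, keep, drop = FALSE]
  center <- colMeans(Xr)
  scale <- apply(Xr, 2L, stats::sd)
  Xz <- sweep(sweep(Xr, 2L, center, `-`), 2L, scale, `/`)
  n <- length(y)
  w <- ifelse(y, n / (2 * sum(y)), n / (2 * sum(!y)))
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, Xz), as.numeric(y),
                   weights = w, family = stats::binomial()))
  coefs <- fit$coefficients
  coefs[!is.finite(coefs)] <- 0
  structure(list(beta0 = coefs[1L],
                 beta = coefs[-1L],
                 center = center,
                 scale = scale,
                 retained = colnames(X)[keep],
                 n_features = length(keep),
                 converged = isTRUE(fit$converged)),
            class = "hf_model")
}

#' Pre-ictal probability of samples under a fitted model
#'
#' Computes the logistic model explicitly:
#' `p(x) = 1 / (1 + exp(-(b0 + b1 x1 + ... + bn xn)))` on the z-scored
#' retained columns.
#'
#' @param model an `hf_model`.
#' @param X design matrix with (at least) the model's retained columns.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_probability <- function(model, X) {
  stopifnot(inherits(model, "hf_model"))
  Xr <- X[, model$retained, drop = FALSE]
  Xz <- sweep(sweep(Xr, 2L, model$center, `-`), 2L, model$scale, `/`)
  eta <- model$beta0 + drop(Xz %*% model$beta)
  1 / (1 + exp(-eta))
}

#' @export
print.hf_model <- function(x, ...) {
  cat("<hf_model> logistic regression on", x$n_features,
      "retained columns\n")
  invisible(x)
}
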