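# Hyper-feature time series on the 1-min reference grid, with labels.

# op over v[a:b] for aligned index vectors a, b (cumsum fast paths for
# mean/variance; short explicit loops otherwise)
apply_operator <- function(v, a, b, op) {
  n <- b - a + 1
  if (op == "mean") {
    cs <- c(0, cumsum(v))
    return((cs[b + 1] - cs[a]) / n)
  }
  if (op == "variance") {
    cs <- c(0, cumsum(v))
    cs2 <- c(0, cumsum(v^2))
    s <- cs[b + 1] - cs[a]
    s2 <- cs2[b + 1] - cs2[a]
    return(pmax((s2 - s^2 / n) / (n - 1), 0))
  }
  if (op %in% c("max", "min") &&
      all((a - 1L) %% 12L == 0L) && all(b %% 12L == 0L)) {
    # windows are aligned to whole minutes (12 five-second windows), so
    # per-minute block extrema decompose the window extremum exactly
    nb <- length(v) %/% 12L
    m <- matrix(v[seq_len(nb * 12L)], 12L)
    ext <- if (op == "max") do.call(pmax, asplit(m, 1L))
    else do.call(pmin, asplit(m, 1L))
    ba <- (a - 1L) %/% 12L + 1L
    bb <- b %/% 12L
    f <- if (op == "max") max else min
    return(vapply(seq_along(a), function(i) f(ext[ba[i]:bb[i]]),
                  numeric(1)))
  }
  if (op == "median") {
    return(vapply(seq_along(a), function(i) {
      x <- v[a[i]:b[i]]
      n1 <- length(x)
      h <- (n1 + 1L) %/% 2L
      if (n1 %% 2L == 1L) sort.int(x, partial = h)[h]
      else {
        s <- sort.int(x, partial = c(h, h + 1L))
        (s[h] + s[h + 1L]) / 2
      }
    }, numeric(1)))
  }
  f <- switch(op, max = max, min = min,
              stop("unknown operator: ", op))
  vapply(seq_along(a), function(i) f(v[a[i]:b[i]]), numeric(1))
}

# one hyper-feature column on its full feasible minute grid, cached per
# (recipe x segment) because the GA revisits gene tuples constantly
hf_column <- function(tensor, feature, electrode, operator, window_min,
                      instant_min, cache = NULL, segment_id = NULL) {
  W <- dim(tensor$values)[1L]
  k_lo <- instant_min + window_min
  k_hi <- instant_min + W %/% 12L
  key <- NULL
  if (!is.null(cache)) {
    key <- paste(segment_id, feature, electrode, operator, window_min,
                 instant_min, sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  ks <- seq.int(k_lo, k_hi)
  b <- 12L * (ks - instant_min)                 # last 5-s window index
  a <- b - 12L * window_min + 1L
  v <- tensor$values[, electrode, feature]
  col <- apply_operator(v, a, b, operator)
  out <- list(ks = ks, values = col)
  if (!is.null(cache)) cache[[key]] <- out
  out
}

label_grid <- function(times, onsets, pre_ictal_min, sph_min,
                       post_guard_min = 30) {
  lab <- rep("interictal", length(times))
  for (o in onsets) {
    lab[times >= o - pre_ictal_min * 60 & times < o - sph_min * 60] <- "preictal"
  }
  for (o in onsets) {
    lab[times >= o - sph_min * 60 & times <= o + post_guard_min * 60] <- "excluded"
  }
  lab
}

#' Build the hyper-feature series of a decoded individual
#'
#' At each 1-min reference time `r`, hyper-feature `i` is its operator
#' applied to the decoded first-level feature over the 5-s windows in
#' `[r - t_i - w_i, r - t_i)` (offset `t_i`, window `w_i` minutes). Rows
#' whose aggregation window would extend outside the recorded data are
#' excluded. Labels: `preictal` on `[onset - pre_ictal, onset - SPH)`,
#' `excluded` on `[onset - SPH, onset + post-ictal guard]`, else
#' `interictal`.
#'
#' @param tensor a `feature_tensor`.
#' @param phenotype a decoded [decode_individual()] phenotype.
#' @param onsets seizure onsets of the segment, seconds.
#' @param cache optional environment memoizing hyper-feature columns.
#' @param segment_id cache namespace for this segment.
#' @param post_guard_min post-ictal guard excluded after onset (minutes).
#' @return an `hf_series`: list with `times` (s), `X` (rows x 5 matrix),
#'   `labels`, `onsets`, and the phenotype's timing fields.
#' @export
build_series <- function(tensor, phenotype, onsets, cache = NULL,
                         segment_id = NULL, post_guard_min = 30) {
  stopifnot(inherits(tensor, "feature_tensor"), inherits(phenotype, "phenotype"))
  rec <- phenotype$recipes
  if (!all(rec$electrode %in% tensor$electrodes))
    stop("tensor does not cover electrodes: ",
         paste(setdiff(rec$electrode, tensor$electrodes), collapse = ", "))
  W <- dim(tensor$values)[1L]
  k_min <- max(rec$instant_min + rec$window_min)
  k_max <- W %/% 12L + min(rec$instant_min)
  if (k_max < k_min) stop("record too short for this phenotype")
  ks <- seq.int(k_min, k_max)
  X <- matrix(NA_real_, length(ks), 5L,
              dimnames = list(NULL, paste0("hf", 1:5)))
  for (i in 1:5) {
    col <- hf_column(tensor, rec$feature[i], rec$electrode[i],
                     rec$operator[i], rec$window_min[i], rec$instant_min[i],
                     cache = cache, segment_id = segment_id)
    X[, i] <- col$values[match(ks, col$ks)]
  }
  times <- ks * 60
  structure(list(times = times, X = X,
                 labels = label_grid(times, onsets,
                                     phenotype$pre_ictal_min,
                                     phenotype$sph_min, post_guard_min),
                 onsets = onsets,
                 pre_ictal_min = phenotype$pre_ictal_min,
                 sop_min = phenotype$sop_min,
                 sph_min = phenotype$sph_min),
            class = "hf_series")
}

#' Add lagged copies of every hyper-feature column
#'
#' Each column is replicated at the given lags on the 1-min grid (default
#' 1, 2, 3 min, giving 20 columns from 5), turning static hyper-features
#' into temporal ones; the first `max(lags)` rows, whose lagged values
#' would precede the series, are dropped.
#'
#' @param series an `hf_series`.
#' @param lags positive integer lags in minutes.
#' @return the lag-expanded `hf_series`.
#' @export
add_lags <- function(series, lags = 1:3) {
  stopifnot(inherits(series, "hf_series"))
  n <- nrow(series$X)
  m <- max(lags)
  if (n <= m) stop("series must be longer than the largest lag (>= ",
                   m + 1, " rows)")
  keep <- (m + 1L):n
  cols <- list()
  for (l in c(0L, as.integer(lags))) {
    Xl <- series$X[keep - l, , drop = FALSE]
    colnames(Xl) <- paste0(colnames(series$X), "_lag", l)
    cols[[as.character(l)]] <- Xl
  }
  series$X <- do.call(cbind, cols)
  series$times <- series$times[keep]
  series$labels <- series$labels[keep]
  series$lags <- c(0L, as.integer(lags))
  series
}
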