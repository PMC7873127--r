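# Phenotype (interpretability) study: presence and predictive power of gene
# values across the best individuals of a set of executions, with
# electrode -> lobe / hemisphere roll-ups and co-occurrence summaries.

phenotype_dimensions <- function(domains, anatomy) {
  list(feature = feature_names(),
       operator = domains$genes$math_operator$values,
       electrode = domains$genes$electrode$values,
       lobe = unique(anatomy$lobe),
       hemisphere = unique(anatomy$hemisphere),
       window_length = domains$genes$window_length$values,
       time_instant = domains$genes$time_instant$values)
}

# per hyper-feature, the value it carries in each phenotype dimension;
# the dominant flag masks the non-expressed feature gene entirely
hf_dimension_values <- function(ind, anatomy) {
  lapply(ind$hyper_features, function(h) {
    elec <- h$electrode
    row <- anatomy[anatomy$electrode == elec, , drop = FALSE]
    list(feature = decoded_feature(h),
         operator = h$math_operator,
         electrode = elec,
         lobe = row$lobe[1L],
         hemisphere = row$hemisphere[1L],
         window_length = as.character(h$window_length),
         time_instant = as.character(h$time_instant))
  })
}

weighted_dimension_scores <- function(ind, weights, domains, anatomy) {
  dims <- phenotype_dimensions(domains, anatomy)
  vals <- hf_dimension_values(ind, anatomy)
  out <- lapply(names(dims), function(d) {
    v <- stats::setNames(numeric(length(dims[[d]])), dims[[d]])
    for (i in 1:5) v[vals[[i]][[d]]] <- v[vals[[i]][[d]]] + weights[i]
    tot <- sum(v)
    if (tot > 0) v / tot else v
  })
  stats::setNames(out, names(dims))
}

#' Normalized presence of gene values in one individual
#'
#' Each hyper-feature contributes a binary indicator for the value it
#' carries in every phenotype dimension (decoded feature, operator,
#' electrode, lobe, hemisphere, window length, time instant); the
#' non-expressed feature gene contributes nothing. Indicators are summed
#' over the five hyper-features and normalized to sum to 1 per dimension.
#'
#' @param ind an `individual`.
#' @param domains a [gene_domains()] object.
#' @param anatomy electrode->lobe/hemisphere map (see
#'   [electrode_anatomy()]).
#' @return named list of normalized presence vectors, one per dimension.
#' @export
gene_presence <- function(ind, domains = gene_domains(),
                          anatomy = electrode_anatomy(domains$genes$electrode$values)) {
  weighted_dimension_scores(ind, rep(1, 5), domains, anatomy)
}

#' Normalized predictive power of gene values in one individual
#'
#' A hyper-feature's scalar weight is the mean absolute logistic-regression
#' coefficient over its retained (lagged) columns (0 if every column was
#' filtered out); a gene value's score is the summed weight of the
#' hyper-features carrying it, normalized per dimension.
#'
#' @param ind an `individual`.
#' @param model the fitted `hf_model` for this individual (the deployed
#'   model, trained on all training seizures).
#' @param collapse how several lagged coefficients collapse to one weight:
#'   `"mean"` (default) or `"sum"`.
#' @inheritParams gene_presence
#' @return named list of normalized predictive-power vectors.
#' @export
gene_predictive_power <- function(ind, model, domains = gene_domains(),
                                  anatomy = electrode_anatomy(domains$genes$electrode$values),
                                  collapse = c("mean", "sum")) {
  collapse <- match.arg(collapse)
  stopifnot(inherits(model, "hf_model"))
  weights <- vapply(1:5, function(i) {
    cols <- grep(paste0("^hf", i, "_lag"), model$retained)
    if (!length(cols)) return(0)
    b <- abs(model$beta[cols])
    if (collapse == "mean") mean(b) else sum(b)
  }, numeric(1))
  weighted_dimension_scores(ind, weights, domains, anatomy)
}

#' Aggregate phenotype report over a set of executions
#'
#' Averages the per-individual normalized presence and predictive-power
#' vectors over all individuals (typically the 30 best-of-execution
#' individuals) and summarizes co-occurrence: the histograms of distinct
#' window lengths, distinct time instants and distinct lobes per
#' individual.
#'
#' @param individuals list of `individual`s.
#' @param models matching list of fitted `hf_model`s.
#' @inheritParams gene_predictive_power
#' @return a `phenotype_report` with `presence`, `power` (named lists of
#'   normalized vectors) and `cooccurrence` (named list of histograms).
#' @export
phenotype_report <- function(individuals, models, domains = gene_domains(),
                             anatomy = electrode_anatomy(domains$genes$electrode$values),
                             collapse = "mean") {
  stopifnot(length(individuals) >= 1L,
            length(individuals) == length(models))
  pres <- lapply(individuals, gene_presence, domains = domains,
                 anatomy = anatomy)
  pow <- lapply(seq_along(individuals), function(i)
    gene_predictive_power(individuals[[i]], models[[i]], domains = domains,
                          anatomy = anatomy, collapse = collapse))
  avg <- function(lst) {
    dims <- names(lst[[1L]])
    out <- lapply(dims, function(d)
      Reduce(`+`, lapply(lst, `[[`, d)) / length(lst))
    stats::setNames(out, dims)
  }
  distinct_hist <- function(dim, max_k = 5L) {
    counts <- vapply(individuals, function(ind) {
      vals <- vapply(hf_dimension_values(ind, anatomy), `[[`, character(1),
                     dim)
      length(unique(vals))
    }, integer(1))
    tab <- stats::setNames(integer(max_k), as.character(seq_len(max_k)))
    t0 <- table(counts)
    tab[names(t0)] <- as.integer(t0)
    tab
  }
  structure(list(presence = avg(pres), power = avg(pow),
                 cooccurrence = list(
                   window_lengths = distinct_hist("window_length"),
                   time_instants = distinct_hist("time_instant"),
                   lobes = distinct_hist("lobe")),
                 n_individuals = length(individuals)),
            class = "phenotype_report")
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat("<phenotype_report> over", x$n_individuals, "individual(s)\n")
  for (d in names(x$power)) {
    v <- sort(x$power[[d]], decreasing = TRUE)
    v <- v[v > 0]
    cat(sprintf("  %-14s top: %s\n", d,
                paste(sprintf("%s (%.2f)", names(head(v, 3)), head(v, 3)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Bar-chart rendering of a phenotype report dimension
#'
#' Presence and predictive power side by side for one dimension.
#'
#' @param x a `phenotype_report`.
#' @param dimension which dimension to plot (default `"electrode"`).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.phenotype_report <- function(x, dimension = "electrode", ...) {
  m <- rbind(presence = x$presence[[dimension]],
             power = x$power[[dimension]])
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    las = 2, main = dimension, ...)
  invisible(x)
}

#' Persist a phenotype report as CSV tables plus a JSON summary
#'
#' @param report a `phenotype_report`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_phenotype_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, lapply(names(report$presence), function(d)
    data.frame(dimension = d, value = names(report$presence[[d]]),
               presence = as.numeric(report$presence[[d]]),
               predictive_power = as.numeric(report$power[[d]]))))
  csv_path <- file.path(dir, "phenotype.csv")
  utils::write.csv(rows, csv_path, row.names = FALSE)
  json_path <- file.path(dir, "phenotype.json")
  jsonlite::write_json(list(presence = report$presence,
                            power = report$power,
                            cooccurrence = report$cooccurrence,
                            n_individuals = report$n_individuals),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
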