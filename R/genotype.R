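# Individuals: five 7-gene hyper-features, decoding, mutation, recombination.

new_individual <- function(hyper_features, fitness = NA_real_) {
  stopifnot(length(hyper_features) == 5L)
  structure(list(hyper_features = hyper_features, fitness = fitness),
            class = "individual")
}

#' Draw a random individual
#'
#' Every gene of each of the five hyper-features is drawn uniformly from its
#' domain; fitness is unset.
#'
#' @param domains a [gene_domains()] object.
#' @return an `individual`.
#' @export
random_individual <- function(domains) {
  hf <- lapply(1:5, function(i) {
    g <- lapply(domains$genes, function(gd)
      gd$values[sample.int(length(gd$values), 1L)])
    names(g) <- gene_names()
    g
  })
  new_individual(hf)
}

#' @export
print.individual <- function(x, ...) {
  cat("<individual> fitness:",
      if (is.na(x$fitness)) "unset" else format(x$fitness, digits = 4), "\n")
  for (i in 1:5) {
    h <- x$hyper_features[[i]]
    feat <- if (h$dominant_feature == "band_wave")
      paste0("rel_power_", sub("rel_power_", "", h$band_wave_feature))
    else h$non_band_wave_feature
    cat(sprintf("  hf%d: %s(%s @ %s), window %s min, instant %s min\n",
                i, h$math_operator, feat, h$electrode,
                h$window_length, h$time_instant))
  }
  invisible(x)
}

# resolved (expressed) first-level feature of one hyper-feature
decoded_feature <- function(hf) {
  if (hf$dominant_feature == "band_wave") hf$band_wave_feature
  else hf$non_band_wave_feature
}

#' Decode a genotype into its phenotype
#'
#' The dominant-feature flag selects which of the two feature genes is
#' expressed; hyper-features are placed chronologically by their time
#' instant. The pre-ictal period is the minimum pre-ictal period plus the
#' largest time instant (the distance from the first chronological
#' hyper-feature to the seizure); SOP = pre-ictal - SPH.
#'
#' @param ind an `individual`.
#' @param min_preictal minimum pre-ictal period in minutes (40, 50 or 60
#'   in the reference configuration).
#' @param sph_min seizure prediction horizon in minutes (default 10).
#' @return a `phenotype`: list with a `recipes` data.frame (feature,
#'   electrode, operator, window and offset per hyper-feature) and
#'   `pre_ictal_min`, `sop_min`, `sph_min`.
#' @export
decode_individual <- function(ind, min_preictal, sph_min = 10) {
  stopifnot(inherits(ind, "individual"))
  recipes <- do.call(rbind, lapply(ind$hyper_features, function(h) {
    data.frame(feature = decoded_feature(h),
               electrode = h$electrode,
               operator = h$math_operator,
               window_min = as.numeric(h$window_length),
               instant_min = as.numeric(h$time_instant),
               stringsAsFactors = FALSE)
  }))
  pre_ictal <- min_preictal + max(recipes$instant_min)
  sop <- pre_ictal - sph_min
  if (sop <= 0) stop("SOP must be positive: pre-ictal ", pre_ictal,
                     " min with SPH ", sph_min, " min")
  structure(list(recipes = recipes, pre_ictal_min = pre_ictal,
                 sop_min = sop, sph_min = sph_min),
            class = "phenotype")
}

#' Mutate an individual by one unitary neighbourhood step
#'
#' One hyper-feature is chosen at random, then one of its genes, and the
#' gene value moves to a uniformly chosen neighbour in that gene's graph;
#' everything else is untouched, so the gene-tuple Hamming distance between
#' input and output is exactly 1.
#'
#' @param ind an `individual`.
#' @param domains a [gene_domains()] object.
#' @return the mutated `individual` (fitness unset).
#' @export
mutate_individual <- function(ind, domains) {
  hf_i <- sample.int(5L, 1L)
  gene <- gene_names()[sample.int(7L, 1L)]
  gd <- domains$genes[[gene]]
  cur <- match(ind$hyper_features[[hf_i]][[gene]], gd$values)
  nb <- gd$adjacency[[cur]]
  ind$hyper_features[[hf_i]][[gene]] <- gd$values[nb[sample.int(length(nb), 1L)]]
  ind$fitness <- NA_real_
  ind
}

# pairing rule for recombination: rank hyper-features by time instant
# (ties by electrode domain order, then original slot) and pair by rank,
# preserving the temporal-sequence structure through crossover
hf_order <- function(ind, domains) {
  instants <- vapply(ind$hyper_features,
                     function(h) as.numeric(h$time_instant), numeric(1))
  elec <- vapply(ind$hyper_features,
                 function(h) match(h$electrode,
                                   domains$genes$electrode$values),
                 numeric(1))
  order(instants, elec, seq_len(5L))
}

#' Recombine two parents into one offspring
#'
#' Hyper-features are first paired across the parents (by time-instant
#' rank), then each offspring gene value is drawn uniformly from the nodes
#' on the shortest paths between the two parent values in that gene's
#' neighbourhood graph. Identical parents therefore reproduce themselves.
#'
#' @param parent_a,parent_b `individual`s.
#' @param domains a [gene_domains()] object.
#' @return the offspring `individual` (fitness unset).
#' @export
recombine_individuals <- function(parent_a, parent_b, domains) {
  oa <- hf_order(parent_a, domains)
  ob <- hf_order(parent_b, domains)
  hf <- vector("list", 5L)
  for (r in 1:5) {
    ha <- parent_a$hyper_features[[oa[r]]]
    hb <- parent_b$hyper_features[[ob[r]]]
    g <- lapply(gene_names(), function(gene)
      shortest_path_choice(domains, gene, ha[[gene]], hb[[gene]]))
    names(g) <- gene_names()
    # the r-th ranked pair lands in the slot of parent A's r-th ranked
    # hyper-feature, so identical parents reproduce themselves exactly
    hf[[oa[r]]] <- g
  }
  new_individual(hf)
}

#' Gene-tuple Hamming distance between two individuals
#'
#' Counts, slot by slot, the genes on which the two genotypes differ
#' (35 gene positions in total).
#'
#' @param a,b `individual`s.
#' @return integer in 0..35.
#' @export
genotype_distance <- function(a, b) {
  sum(vapply(1:5, function(i)
    sum(vapply(gene_names(), function(g)
      !identical(as.character(a$hyper_features[[i]][[g]]),
                 as.character(b$hyper_features[[i]][[g]])),
      logical(1))), integer(1)))
}

genotype_key <- function(ind) {
  paste(vapply(ind$hyper_features,
               function(h) paste(unlist(h[gene_names()]), collapse = "|"),
               character(1)), collapse = "||")
}

#' Serialize / deserialize an individual as JSON
#'
#' Genotypes are stored as an array of five gene-name/value records plus
#' the cached fitness, for audit and reuse.
#'
#' @param ind an `individual`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return JSON string (or `path` invisibly).
#' @export
individual_to_json <- function(ind, path = NULL) {
  obj <- list(hyper_features = lapply(ind$hyper_features,
                                      function(h) h[gene_names()]),
              fitness = ind$fitness)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname individual_to_json
#' @param json JSON string or file path produced by [individual_to_json()].
#' @export
individual_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  hf <- lapply(obj$hyper_features, function(h) {
    h <- h[gene_names()]
    names(h) <- gene_names()
    h
  })
  fit <- obj$fitness
  new_individual(hf, fitness = if (is.null(fit)) NA_real_ else as.numeric(fit))
}
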