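# Gene domains and neighbourhood graphs for the 7-gene hyper-feature code.
#
# Ordinal genes (window length, time instant) and the ordered categorical
# genes (band, non-band feature, operator) use chain graphs in their natural
# order; the electrode gene uses the 10-20 spatial adjacency graph; the
# dominant flag is a 2-node graph. Shortest-path node sets between every
# value pair are precomputed (igraph) so recombination is a table lookup.

chain_edges <- function(values) {
  if (length(values) < 2L) return(matrix(character(0), ncol = 2))
  cbind(values[-length(values)], values[-1L])
}

build_gene <- function(values, edges) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  missing <- setdiff(values, igraph::V(g)$name)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing),
                                                 name = missing)
  if (igraph::components(g)$no != 1L)
    stop("gene neighbourhood graph must be connected")
  k <- length(values)
  vids <- match(values, igraph::V(g)$name)
  adj <- lapply(seq_len(k), function(i) {
    nb <- igraph::neighbors(g, vids[i])$name
    match(nb, values)
  })
  sp <- vector("list", k)
  for (u in seq_len(k)) {
    sp[[u]] <- vector("list", k)
    for (v in seq_len(k)) {
      if (u == v) { sp[[u]][[v]] <- u; next }
      paths <- igraph::all_shortest_paths(g, from = vids[u], to = vids[v])$vpaths
      nodes <- unique(unlist(lapply(paths, function(p) p$name)))
      sp[[u]][[v]] <- match(nodes, values)
    }
  }
  list(values = values, adjacency = adj, shortest_paths = sp)
}

#' Gene domains and neighbourhood graphs for the hyper-feature genotype
#'
#' Builds the seven gene domains: dominant-feature flag, band-wave feature
#' (the 7 relative powers, chained in frequency order), non-band-wave
#' feature, mathematical operator, electrode (10-20 spatial adjacency),
#' window length and time instant (chains). All value sets are
#' configurable; every graph is connected by construction.
#'
#' @param electrodes electrode labels (default: full 10-20 montage). A
#'   subset that cuts the montage adjacency into pieces is re-connected by
#'   bridging the components in listed order.
#' @param operators aggregation operators (default
#'   `mean, median, variance, max, min`).
#' @param window_lengths hyper-feature window lengths in minutes.
#' @param time_instants offsets in minutes before the minimum pre-ictal
#'   boundary.
#' @param electrode_graph optional 2-column edge matrix overriding the
#'   10-20 adjacency (must keep the graph connected).
#' @return a `gene_domains` object.
#' @export
gene_domains <- function(electrodes = montage_1020(),
                         operators = c("mean", "median", "variance",
                                       "max", "min"),
                         window_lengths = c(1, 5, 10, 15, 20),
                         time_instants = 0:20,
                         electrode_graph = NULL) {
  stopifnot(length(electrodes) >= 1L, length(operators) >= 1L,
            length(window_lengths) >= 1L, length(time_instants) >= 1L)
  edges <- electrode_graph %||% electrode_edges()
  keep <- edges[, 1L] %in% electrodes & edges[, 2L] %in% electrodes
  if (is.null(electrode_graph) && length(electrodes) > 1L) {
    # a montage subset can cut the 10-20 adjacency into pieces; bridge the
    # components in listed order so every gene graph stays connected
    comp <- components_of(electrodes, edges[keep, , drop = FALSE])
    if (length(comp) > 1L) {
      bridges <- do.call(rbind, lapply(seq_len(length(comp) - 1L),
                                       function(i) c(comp[[i]][1L],
                                                     comp[[i + 1L]][1L])))
      edges <- rbind(edges, bridges)
      keep <- c(keep, rep(TRUE, nrow(bridges)))
    }
  }
  genes <- list(
    dominant_feature = build_gene(c("band_wave", "non_band_wave"),
                                  chain_edges(c("band_wave", "non_band_wave"))),
    band_wave_feature = build_gene(band_features(),
                                   chain_edges(band_features())),
    non_band_wave_feature = build_gene(non_band_features(),
                                       chain_edges(non_band_features())),
    math_operator = build_gene(operators, chain_edges(operators)),
    electrode = build_gene(electrodes,
                           if (length(electrodes) > 1L)
                             edges[keep, , drop = FALSE]
                           else matrix(character(0), ncol = 2)),
    window_length = build_gene(as.character(window_lengths),
                               chain_edges(as.character(window_lengths))),
    time_instant = build_gene(as.character(time_instants),
                              chain_edges(as.character(time_instants))))
  structure(list(genes = genes), class = "gene_domains")
}

# connected components of a vertex set under an edge list, in vertex order
components_of <- function(vertices, edges) {
  comp <- as.list(vertices)
  find <- function(v) which(vapply(comp, function(c) v %in% c, logical(1)))
  for (r in seq_len(nrow(edges))) {
    i <- find(edges[r, 1L]); j <- find(edges[r, 2L])
    if (i != j) {
      comp[[min(i, j)]] <- c(comp[[min(i, j)]], comp[[max(i, j)]])
      comp[[max(i, j)]] <- NULL
    }
  }
  comp
}

gene_names <- function() {
  c("dominant_feature", "band_wave_feature", "non_band_wave_feature",
    "math_operator", "electrode", "window_length", "time_instant")
}

#' Uniform choice on the shortest paths between two gene values
#'
#' Draws uniformly from the union of nodes lying on any shortest path
#' between `u` and `v` in the gene's neighbourhood graph (endpoints
#' included); with `u == v` the value is returned unchanged. This is the
#' per-gene recombination rule.
#'
#' @param domains a `gene_domains` object.
#' @param gene gene name (one of `gene_names()`).
#' @param u,v parent gene values.
#' @return one gene value.
#' @export
shortest_path_choice <- function(domains, gene, u, v) {
  gd <- domains$genes[[gene]]
  ui <- match(as.character(u), gd$values)
  vi <- match(as.character(v), gd$values)
  if (is.na(ui) || is.na(vi)) stop("value outside gene domain for ", gene)
  cand <- gd$shortest_paths[[ui]][[vi]]
  gd$values[cand[sample.int(length(cand), 1L)]]
}
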