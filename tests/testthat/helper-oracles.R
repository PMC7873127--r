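# Independent oracles kept deliberately separate from the implementation.

# brute-force rectangular-window periodogram (one-sided density)
brute_periodogram <- function(x, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / (n * fs)
  nf <- n %/% 2 + 1
  psd <- sp[seq_len(nf)]
  if (nf > 2) psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  list(freq = (seq_len(nf) - 1) * fs / n, psd = psd)
}

brute_band_fraction <- function(x, fs, low, high) {
  p <- brute_periodogram(x, fs)
  tot <- p$freq >= 0.5 & p$freq <= 90
  sum(p$psd[p$freq >= low & p$freq <= high & tot]) / sum(p$psd[tot])
}

# BFS distances over an adjacency list (list of integer neighbour vectors)
bfs_distances <- function(adj, start) {
  d <- rep(NA_integer_, length(adj))
  d[start] <- 0L
  frontier <- start
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) for (v in adj[[u]]) if (is.na(d[v])) {
      d[v] <- d[u] + 1L
      nxt <- c(nxt, v)
    }
    frontier <- unique(nxt)
  }
  d
}

# nodes lying on at least one shortest u-v path:
# w is on a shortest path iff d(u,w) + d(w,v) == d(u,v)
bfs_shortest_path_nodes <- function(adj, u, v) {
  du <- bfs_distances(adj, u)
  dv <- bfs_distances(adj, v)
  which(du + dv == du[v])
}

# adjacency list of a gene domain as stored by the package
gene_adjacency <- function(domains, gene) domains$genes[[gene]]$adjacency

# brute-force trailing moving mean (Firing Power oracle)
brute_moving_mean <- function(x, w) {
  vapply(seq_along(x), function(k) mean(x[max(1, k - w + 1):k]), numeric(1))
}

# Welch two-sample t statistic from the textbook formula
welch_t_stat <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}
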