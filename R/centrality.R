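#' Consensus centrality of network nodes
#'
#' Computes three centrality measures per node — degree, shortest-path
#' betweenness (Brandes accumulation, unweighted edges) and closeness in its
#' harmonic form `sum_{u != v} 1/d(u, v)` with `1/Inf = 0` (well defined on
#' the disconnected graphs typical of reconstructed association networks) —
#' ranks each measure descending with average ranks on ties, and defines the
#' consensus centrality of a node as the mean of its three ranks (1 = most
#' central).
#'
#' @param network a `gene_network` or an igraph graph.
#' @return Data frame: `gene`, `degree`, `betweenness`, `closeness`,
#'   `rank_degree`, `rank_betweenness`, `rank_closeness`, `consensus`.
#' @export
compute_centralities <- function(network) {
  g <- if (inherits(network, "gene_network")) as_igraph(network) else network
  n <- igraph::vcount(g)
  if (n == 0) stop("empty node set")
  if (n < 2) stop("need at least 2 nodes")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  clo <- igraph::harmonic_centrality(g, weights = NA, normalized = FALSE)
  rk <- function(x) rank(-x, ties.method = "average")
  out <- data.frame(gene = igraph::V(g)$name,
                    degree = as.numeric(deg),
                    betweenness = as.numeric(btw),
                    closeness = as.numeric(clo),
                    rank_degree = rk(deg),
                    rank_betweenness = rk(btw),
                    rank_closeness = rk(clo),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$consensus <- (out$rank_degree + out$rank_betweenness +
                      out$rank_closeness) / 3
  out
}

#' Select the top fraction of nodes by consensus centrality
#'
#' `k = round(fraction * N)` rounding half away from zero (the convention
#' consistent with selecting 313 of 6256, 285 of 5709 and 343 of 6859 at 5%),
#' with a floor of 1; returns the `k` genes with the smallest consensus rank,
#' ties at the boundary broken by consensus then lexicographic gene id.
#'
#' @param table a [compute_centralities()] table.
#' @param fraction fraction of nodes to select, in (0, 1]; default 0.05.
#' @return Character vector of `k` gene ids.
#' @export
top_fraction <- function(table, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  N <- nrow(table)
  k <- max(1L, as.integer(floor(fraction * N + 0.5)))
  ord <- order(table$consensus, table$gene)
  table$gene[ord][seq_len(k)]
}
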