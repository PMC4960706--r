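# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# step-up FDR adjustment computed directly from the definition
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  sp <- p[ord]
  val <- sp * n / seq_len(n)
  adj <- numeric(n)
  for (i in n:1) adj[i] <- if (i == n) min(val[n], 1) else min(adj[i + 1], val[i], 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

# upper-tail hypergeometric by direct summation over 2x2 tables
hyper_tail_oracle <- function(hits, set_size, universe, query_size) {
  kmax <- min(set_size, query_size)
  if (hits > kmax) return(0)
  sum(sapply(hits:kmax, function(k)
    choose(set_size, k) * choose(universe - set_size, query_size - k))) /
    choose(universe, query_size)
}

# BFS distances and shortest-path counts from a source over an adjacency list
bfs_paths <- function(adj, s) {
  n <- length(adj)
  dist <- rep(Inf, n); sigma <- rep(0, n)
  dist[s] <- 0; sigma[s] <- 1
  q <- s
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; q <- c(q, w) }
      if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
    }
  }
  list(dist = dist, sigma = sigma)
}

adjacency_list <- function(n, edges) {
  adj <- rep(list(integer(0)), n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# betweenness by enumerating pair dependencies over all unordered pairs
betweenness_oracle <- function(n, edges) {
  adj <- adjacency_list(n, edges)
  bfs <- lapply(seq_len(n), function(s) bfs_paths(adj, s))
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (is.infinite(bfs[[s]]$dist[t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (bfs[[s]]$dist[v] + bfs[[t]]$dist[v] == bfs[[s]]$dist[t])
        btw[v] <- btw[v] + bfs[[s]]$sigma[v] * bfs[[t]]$sigma[v] / bfs[[s]]$sigma[t]
    }
  }
  btw
}

harmonic_oracle <- function(n, edges) {
  adj <- adjacency_list(n, edges)
  sapply(seq_len(n), function(s) {
    d <- bfs_paths(adj, s)$dist
    sum(1 / d[-s][is.finite(d[-s])])
  })
}

# truncated-power construction of the natural cubic spline space (intercept,
# linear term, and K-2 natural truncated cubics over K knots)
natural_tp_basis <- function(x, knots) {
  K <- length(knots)
  dk <- function(t, k)
    (pmax(t - knots[k], 0)^3 - pmax(t - knots[K], 0)^3) / (knots[K] - knots[k])
  cols <- cbind(1, x)
  for (k in seq_len(K - 2)) cols <- cbind(cols, dk(x, k) - dk(x, K - 1))
  cols
}

hat_matrix <- function(X) X %*% solve(crossprod(X)) %*% t(X)

# draws from the null density of sample partial correlations at kappa df
sample_null_pcor <- function(n, kappa) {
  (2 * stats::rbinom(n, 1, 0.5) - 1) * sqrt(stats::rbeta(n, 0.5, (kappa - 1) / 2))
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# labels (true edge or not) and a score vector for all unordered pairs of P
edge_truth_labels <- function(P, true_edges) {
  idx <- which(upper.tri(P), arr.ind = TRUE)
  g <- rownames(P)
  edge_key(g[idx[, 1]], g[idx[, 2]]) %in%
    edge_key(true_edges$gene_a, true_edges$gene_b)
}
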