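test_that("trapezoid weights follow the half-interval formula", {
  expect_equal(trapezoid_weights(c(1, 2, 3, 4)), c(1, 2, 2, 1) / 6)
  expect_equal(trapezoid_weights(c(3, 10)), c(0.5, 0.5))
  w <- trapezoid_weights(c(0.25, 2, 7, 12, 24, 48, 72, 96))
  expect_equal(sum(w), 1)
  expect_true(all(w > 0))
  expect_error(trapezoid_weights(c(1, 1, 2)), "strictly increasing")
  expect_error(trapezoid_weights(5), "at least 2")
})

test_that("dynamical correlation matches the weighted hand formula", {
  times <- c(1, 3, 6, 10)
  traj <- rbind(gA = c(1, 2, 4, 3), gB = c(2, 1, 5, 4), gC = c(-1, 0, 2, 1))
  w <- trapezoid_weights(times)
  # spreadsheet-style computation of the weighted correlation
  hand <- function(x, y) {
    xc <- x - sum(w * x); yc <- y - sum(w * y)
    sum(w * xc * yc) / sqrt(sum(w * xc^2) * sum(w * yc^2))
  }
  R <- dynamical_correlation(traj, times)
  for (i in 1:3) for (j in 1:3)
    expect_equal(R[i, j], hand(traj[i, ], traj[j, ]), tolerance = 1e-12)
  expect_equal(diag(R), c(gA = 1, gB = 1, gC = 1))
  Rneg <- dynamical_correlation(rbind(traj, gD = -traj["gA", ]), times)
  expect_equal(unname(Rneg["gA", "gD"]), -1, tolerance = 1e-12)
})

test_that("flat trajectories get zero correlations with a warning", {
  times <- c(1, 2, 4, 8)
  traj <- rbind(gA = c(1, 2, 3, 4), gFlat = c(2, 2, 2, 2))
  expect_warning(R <- dynamical_correlation(traj, times), "zero weighted variance")
  expect_equal(unname(R["gA", "gFlat"]), 0)
})

test_that("shrinkage intensity matches a brute-force evaluation", {
  set.seed(101)
  x <- matrix(rnorm(20 * 5), 20, 5)
  sh <- shrink_correlation(x)
  # brute force: standardized cross-products over observations
  n <- nrow(x); p <- ncol(x)
  xs <- scale(x)
  num <- 0; den <- 0
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    wk <- xs[, i] * xs[, j]
    r <- sum(wk) / (n - 1)
    num <- num + n / (n - 1)^3 * sum((wk - mean(wk))^2)
    den <- den + r^2
  }
  expect_equal(sh$lambda, min(1, num / den), tolerance = 1e-10)
  expect_equal(sh$R, (1 - sh$lambda) * sh$r_raw + sh$lambda * diag(p),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("degenerate shrinkage cases behave as defined", {
  set.seed(5)
  x <- matrix(rnorm(12), 4, 3)
  sh <- shrink_correlation(x)
  expect_true(sh$lambda >= 0 && sh$lambda <= 1)
  expect_error(shrink_correlation(x[1:2, ]), "at least 3")
  # lambda = 1 -> identity -> all partial correlations 0
  P <- partial_correlations(diag(4))
  expect_true(all(P[upper.tri(P)] == 0))
})

test_that("partial correlations invert the shrunken correlation matrix", {
  # 2 variables: partial correlation equals the correlation
  R2 <- matrix(c(1, 0.37, 0.37, 1), 2)
  expect_equal(partial_correlations(R2)[1, 2], 0.37, tolerance = 1e-12)

  # 3-gene chain: marginal A-C nonzero, partial A-C zero
  omega <- ggm_precision(3, rbind(c(1, 2), c(2, 3)), 0.5)
  R <- stats::cov2cor(solve(omega))
  P <- partial_correlations(R)
  expect_gt(abs(R[1, 3]), 0.1)
  expect_lt(abs(P[1, 3]), 1e-12)
  expect_equal(P[1, 2], 0.5, tolerance = 1e-10)

  # involution: the inverse-renormalisation map N(M) = cov2cor(solve(M))
  # applied twice returns the original; partial correlations are its
  # off-diagonal negation
  N <- function(M) stats::cov2cor(solve(M))
  set.seed(91)
  M <- stats::cov2cor(crossprod(matrix(rnorm(36), 6, 6)) + 6 * diag(6))
  expect_equal(N(N(M)), M, tolerance = 1e-10)
  Pm <- partial_correlations(M)
  expect_equal(Pm[upper.tri(Pm)], -N(M)[upper.tri(M)], tolerance = 1e-12)

  expect_error(partial_correlations(matrix(1, 3, 3)), "singular")
})

test_that("edge posterior mixture recovers planted mixture parameters", {
  set.seed(55)
  n <- 5000
  mix <- ifelse(runif(n) < 0.8, sample_null_pcor(n, 50), runif(n, -1, 1))
  m <- fit_edge_posteriors(mix)
  expect_gte(m$eta0, 0.7); expect_lte(m$eta0, 0.9)
  expect_gte(m$kappa, 35); expect_lte(m$kappa, 70)

  # posterior is even in p and minimal at p = 0
  pr <- edge_posterior(m, c(-0.6, -0.2, 0, 0.2, 0.6))
  expect_equal(pr[1], pr[5]); expect_equal(pr[2], pr[4])
  expect_equal(which.min(pr), 3L)
  expect_true(all(diff(edge_posterior(m, seq(0, 0.99, 0.01))) >= -1e-12))
})

test_that("pure-null partial correlations almost never pass the 0.95 posterior", {
  set.seed(56)
  p0 <- sample_null_pcor(5000, 60)
  m <- fit_edge_posteriors(p0)
  expect_lte(mean(edge_posterior(m, p0) >= 0.95), 0.001)
})

test_that("network assembly keeps isolated nodes and respects the threshold", {
  set.seed(21)
  cfg <- sim_config(network_n_nodes = 30, network_n_edges = 12,
                    pcor_magnitude = 0.35, seed = 21)
  nt <- gen_network_timeseries(cfg, n_samples = 150)
  rec <- reconstruct_network(t(nt$expr))
  expect_length(rec$network$nodes, 30)
  expect_true(all(rec$network$edges$prob >= 0.95))

  empty <- build_network(rec$pcor, rec$model, threshold = 1 + 1e-9)
  expect_equal(nrow(empty$edges), 0)
  expect_length(empty$nodes, 30)
})

test_that("true edges stochastically dominate non-edges in |pcor|", {
  cfg <- sim_config(network_n_nodes = 60, network_n_edges = 25,
                    pcor_magnitude = 0.35, seed = 31)
  nt <- gen_network_timeseries(cfg, n_samples = 200)
  rec <- reconstruct_network(t(nt$expr))
  lab <- edge_truth_labels(rec$pcor, nt$truth$true_edges)
  pc <- abs(rec$pcor[upper.tri(rec$pcor)])
  wt <- stats::wilcox.test(pc[lab], pc[!lab], alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("reconstruction is invariant to gene relabeling", {
  cfg <- sim_config(network_n_nodes = 20, network_n_edges = 8,
                    pcor_magnitude = 0.3, seed = 41)
  nt <- gen_network_timeseries(cfg, n_samples = 100)
  x <- t(nt$expr)
  rec <- reconstruct_network(x)
  perm <- sample(ncol(x))
  x2 <- x[, perm]
  rec2 <- reconstruct_network(x2)
  e1 <- with(rec$network$edges, sort(edge_key(gene_a, gene_b)))
  e2 <- with(rec2$network$edges, sort(edge_key(gene_a, gene_b)))
  expect_identical(e1, e2)
  expect_equal(rec$lambda, rec2$lambda, tolerance = 1e-12)
})

test_that("first neighborhood is the induced closed-neighborhood subgraph", {
  # star with 29 leaves around a hub
  leaves <- sprintf("L%02d", 1:29)
  edges <- data.frame(gene_a = pmin("HUB", leaves), gene_b = pmax("HUB", leaves),
                      pcor = 0.4, prob = 0.99, stringsAsFactors = FALSE)
  net <- structure(list(nodes = c("HUB", leaves, "ISO"), edges = edges,
                        threshold = 0.95, model = NULL),
                   class = "gene_network")
  nb <- first_neighborhood(net, "HUB")
  expect_length(nb$nodes, 30)
  expect_equal(nrow(nb$edges), 29)
  iso <- first_neighborhood(net, "ISO")
  expect_equal(iso$nodes, "ISO")
  expect_equal(nrow(iso$edges), 0)
  expect_error(first_neighborhood(net, "nope"), "unknown gene")

  # induced-subgraph property on a random network
  set.seed(61)
  g <- igraph::sample_gnp(15, 0.25)
  el <- igraph::as_edgelist(g)
  nm <- sprintf("g%02d", 1:15)
  redges <- data.frame(gene_a = pmin(nm[el[, 1]], nm[el[, 2]]),
                       gene_b = pmax(nm[el[, 1]], nm[el[, 2]]),
                       pcor = 0.3, prob = 0.99, stringsAsFactors = FALSE)
  rnet <- structure(list(nodes = nm, edges = redges, threshold = 0.95,
                         model = NULL), class = "gene_network")
  for (focal in nm[1:5]) {
    sub <- first_neighborhood(rnet, focal)
    expect_true(all(sub$edges$gene_a %in% sub$nodes))
    expect_true(all(sub$edges$gene_b %in% sub$nodes))
  }
})

test_that("condition switch and trajectory weighting feed the GAN correctly", {
  sim <- gen_timecourse(sim_config(n_genes = 40, prop_de = 0.5, seed = 71))
  for (cond in c("treated", "control", "difference")) {
    traj <- average_trajectories(sim$expr, sim$design, cond)
    expect_equal(dim(traj), c(40, 8))
  }
  gan <- build_gan(sim$expr, sim$design, rownames(sim$expr)[1:20])
  expect_s3_class(gan$network, "gene_network")
  expect_length(gan$network$nodes, 20)
  expect_true(gan$lambda >= 0 && gan$lambda <= 1)
})
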