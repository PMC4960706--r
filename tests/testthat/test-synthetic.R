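test_that("sim_config validates its invariants", {
  expect_error(sim_config(timepoints = c(2, 1, 3)), "strictly increasing")
  expect_error(sim_config(timepoints = c(0, 1, 2, 3, 4)), "positive")
  expect_error(sim_config(prop_de = 1.2), "prop_de")
  expect_error(sim_config(network_n_nodes = 4, network_n_edges = 7), "n\\(n-1\\)/2")
  expect_error(sim_config(pcor_magnitude = 1.1), "pcor_magnitude")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("gen_timecourse honours prop_de and effect_sd edge cases", {
  sim0 <- gen_timecourse(sim_config(n_genes = 50, prop_de = 0, seed = 3))
  expect_length(sim0$truth$de_genes, 0)

  sim_null <- gen_timecourse(sim_config(n_genes = 50, prop_de = 0.5,
                                        effect_sd = 0, seed = 3))
  expect_equal(sim_null$truth$mu_treated, sim_null$truth$mu_control)
})

test_that("regenerating with the same seed is byte-identical; seeds differ", {
  cfg <- sim_config(n_genes = 40, seed = 9)
  a <- gen_timecourse(cfg)
  b <- gen_timecourse(cfg)
  expect_identical(a, b)
  c2 <- gen_timecourse(sim_config(n_genes = 40, seed = 10))
  expect_false(identical(a$expr, c2$expr))
})

test_that("timecourse expression layout matches the design", {
  cfg <- sim_config(n_genes = 20, n_replicates = 3)
  sim <- gen_timecourse(cfg)
  expect_identical(colnames(sim$expr), sim$design$sample)
  expect_equal(ncol(sim$expr), 2 * length(cfg$timepoints) * 3)
  expect_setequal(unique(sim$design$condition), c("control", "treated"))
})

test_that("a 3-node chain yields zero partial but non-zero marginal A-C correlation", {
  edges <- rbind(c(1, 2), c(2, 3))
  omega <- ggm_precision(3, edges, 0.5)
  # hand inversion of the 3x3 precision
  sigma <- solve(omega)
  pc <- -stats::cov2cor(omega)
  expect_equal(pc[1, 2], 0.5)
  expect_equal(pc[2, 3], 0.5)
  expect_equal(-omega[1, 3] / sqrt(omega[1, 1] * omega[3, 3]), 0)
  expect_gt(abs(stats::cov2cor(sigma)[1, 3]), 0.1)
})

test_that("infeasible pcor magnitude errors with the smallest eigenvalue", {
  # K1,4 star at rho = 0.6: min eig of I - rho*A is 1 - 0.6*2 < 0
  star <- cbind(1, 2:5)
  expect_error(ggm_precision(5, star, 0.6), "smallest achievable eigenvalue")
})

test_that("network generator records exact truth and zero-edge case", {
  cfg0 <- sim_config(network_n_nodes = 10, network_n_edges = 0, seed = 2)
  nt0 <- gen_network_timeseries(cfg0, n_samples = 30)
  expect_equal(nrow(nt0$truth$true_edges), 0)
  off <- nt0$truth$pcor[upper.tri(nt0$truth$pcor)]
  expect_true(all(off == 0))

  cfg <- sim_config(network_n_nodes = 30, network_n_edges = 15,
                    pcor_magnitude = 0.3, seed = 4)
  nt <- gen_network_timeseries(cfg, n_samples = 50)
  expect_equal(nrow(nt$truth$true_edges), 15)
  P <- nt$truth$pcor
  lab <- edge_truth_labels(P, nt$truth$true_edges)
  expect_equal(sort(unique(abs(P[upper.tri(P)])[lab])), 0.3)
  expect_true(all(abs(P[upper.tri(P)])[!lab] < 1e-12))
})

test_that("sample covariance converges to the constructed covariance", {
  cfg <- sim_config(network_n_nodes = 15, network_n_edges = 8,
                    pcor_magnitude = 0.3, seed = 6)
  frob <- sapply(c(50, 2000), function(n) {
    nt <- gen_network_timeseries(cfg, n_samples = n)
    norm(stats::cov(t(nt$expr)) - nt$truth$sigma, type = "F")
  })
  expect_lt(frob[2], frob[1])
})

test_that("gene set generator spikes enrichment and validates sizes", {
  universe <- sprintf("g%04d", 1:1000)
  expect_error(gen_gene_sets(universe, size_range = c(10, 2000)), "size_range")
  gs0 <- gen_gene_sets(universe, n_sets = 5, enriched_in = character(0), seed = 2)
  expect_length(gs0$truth$enriched_sets, 0)

  hot <- universe[1:50]
  gs <- gen_gene_sets(universe, n_sets = 10, size_range = c(20, 60),
                      enriched_in = hot, n_enriched = 2, enrich_frac = 1,
                      seed = 5)
  enr <- fisher_enrichment(hot, universe, gs$collection)
  expect_true(all(enr$p[enr$set %in% gs$truth$enriched_sets] < 1e-6))
})

test_that("CNA generator truth equals a linear-scan assignment", {
  genes <- data.frame(gene = sprintf("g%03d", 1:60),
                      chrom = rep(c("chr1", "chr2"), each = 30),
                      midpoint = rep(seq(100, 3000, length.out = 30), 2))
  cna <- gen_cna_profile(genes, n_segments = 5, seed = 3)
  # linear scan oracle over every gene x segment combination
  oracle <- sapply(seq_len(nrow(genes)), function(i) {
    seg <- cna$segments
    hit <- seg$chrom == genes$chrom[i] & seg$start <= genes$midpoint[i] &
      genes$midpoint[i] < seg$end
    if (any(hit)) seg$call[hit] else 0L
  })
  expect_equal(unname(cna$truth[genes$gene]), oracle)
})

test_that("whole-chromosome gain covers every gene on it", {
  genes <- data.frame(gene = letters[1:5], chrom = "chr1",
                      midpoint = c(0, 10, 500, 900, 1200))
  seg <- data.frame(chrom = "chr1", start = 0, end = 2000, call = 1L)
  expect_true(all(map_genes_to_calls(genes, seg)$call == 1))
})

test_that("colony counts follow the linear-quadratic Poisson law", {
  tab <- gen_colony_counts(0, 0, 0.4, doses = c(0, 2, 4), cells_seeded = 5000,
                           n_experiments = 2, seed = 8)
  by_dose <- tapply(tab$colonies / tab$cells_seeded, tab$dose, mean)
  expect_true(all(abs(by_dose - 0.4) < 0.05))  # dose-independent when alpha=beta=0

  expect_error(gen_colony_counts(0.3, 0.03, 0.5, doses = c(-1, 0, 2)),
               "non-negative")
  # closed-form surviving fraction at D=2, alpha=0.3, beta=0.03
  expect_equal(exp(-(0.3 * 2 + 0.03 * 4)), 0.4868, tolerance = 1e-4)
  big <- gen_colony_counts(0.3, 0.03, 0.5, doses = c(0, 2), cells_seeded = 2e5,
                           n_experiments = 1, seed = 12)
  sf <- big$colonies[big$dose == 2] / big$colonies[big$dose == 0]
  expect_equal(mean(sf), exp(-0.72), tolerance = 0.02)
})
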