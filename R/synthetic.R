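#' Simulation configuration for the synthetic radiation-response experiment
#'
#' Bundles every tunable of the synthetic-data generators. Defaults emulate the
#' study design the pipeline targets: two conditions (sham-irradiated control
#' vs irradiated), eight sampling times between 15 min and 96 h, three
#' independent replicate experiments, gene-wise variances drawn from a scaled
#' inverse-chi-square hyperprior, and a sparse Gaussian graphical dependence
#' structure among a subset of genes.
#'
#' @param n_genes number of genes to simulate.
#' @param timepoints strictly increasing, positive sampling times in hours.
#' @param n_replicates replicate experiments per condition.
#' @param prop_de fraction of genes in `[0, 1]` given a treatment effect.
#' @param effect_sd standard deviation (log2 units) of the treatment spline
#'   coefficients for differentially expressed genes.
#' @param baseline_sd standard deviation (log2 units) of the baseline spline
#'   coefficients shared by both conditions.
#' @param d0 prior degrees of freedom of the gene-variance hyperprior.
#' @param s0_sq prior variance scale (log2 units squared).
#' @param network_n_nodes,network_n_edges size of the simulated gene
#'   association network.
#' @param pcor_magnitude absolute partial correlation of true edges, in (0, 1).
#' @param seed integer seed; each generator uses `seed` plus a fixed offset so
#'   adding a generator never perturbs the stream of another.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       timepoints = c(0.25, 2, 7, 12, 24, 48, 72, 96),
                       n_replicates = 3,
                       prop_de = 0.2,
                       effect_sd = 1,
                       baseline_sd = 1,
                       d0 = 4,
                       s0_sq = 0.05,
                       network_n_nodes = 100,
                       network_n_edges = 40,
                       pcor_magnitude = 0.35,
                       seed = 1L) {
  stopifnot(length(n_genes) == 1, n_genes >= 1,
            length(n_replicates) == 1, n_replicates >= 1,
            length(seed) == 1, is.finite(seed))
  if (length(timepoints) < 2 || any(diff(timepoints) <= 0) || any(timepoints <= 0))
    stop("invalid design: `timepoints` must be strictly increasing and positive")
  if (prop_de < 0 || prop_de > 1)
    stop("`prop_de` must lie in [0, 1]")
  if (effect_sd < 0 || baseline_sd < 0)
    stop("coefficient standard deviations must be non-negative")
  if (d0 <= 0 || s0_sq <= 0)
    stop("variance hyperparameters `d0` and `s0_sq` must be positive")
  max_edges <- network_n_nodes * (network_n_nodes - 1) / 2
  if (network_n_edges < 0 || network_n_edges > max_edges)
    stop("`network_n_edges` must be in [0, n(n-1)/2]")
  if (pcor_magnitude <= 0 || pcor_magnitude >= 1)
    stop("`pcor_magnitude` must lie in (0, 1)")
  structure(list(n_genes = as.integer(n_genes), timepoints = as.numeric(timepoints),
                 n_replicates = as.integer(n_replicates), prop_de = prop_de,
                 effect_sd = effect_sd, baseline_sd = baseline_sd,
                 d0 = d0, s0_sq = s0_sq,
                 network_n_nodes = as.integer(network_n_nodes),
                 network_n_edges = as.integer(network_n_edges),
                 pcor_magnitude = pcor_magnitude, seed = as.integer(seed)),
            class = "sim_config")
}

# fixed per-generator seed offsets (one RNG stream per generator)
.seed_offsets <- c(timecourse = 1L, network = 2L, gene_sets = 3L,
                   cna = 4L, colony = 5L)

#' Simulate a two-condition time-course expression experiment
#'
#' Each gene's control trajectory is `intercept + B(t) b_g` where `B` is a
#' 3-df natural cubic spline basis over the design times and `b_g` are random
#' coefficients. Genes selected as differentially expressed additionally get a
#' treatment difference `g0 + B(t) g` (offset plus shape) with coefficients
#' drawn `Normal(0, effect_sd^2)`; all other genes have identical expected
#' trajectories in both conditions. Residual noise is
#' `Normal(0, sigma_g^2)` with `sigma_g^2 ~ d0 * s0_sq / ChiSq(d0)`, the
#' scaled inverse-chi-square hyperprior targeted by the empirical-Bayes
#' moderation stage.
#'
#' @param config a [sim_config()].
#' @return A list with `expr` (genes x samples log2 matrix), `design` (a data
#'   frame with columns sample, condition, time_h, replicate) and `truth`
#'   (list with `de_genes`, per-gene `sigma2`, and the mean matrices).
#' @export
gen_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + .seed_offsets[["timecourse"]])
  tp <- config$timepoints
  G <- config$n_genes
  genes <- sprintf("g%04d", seq_len(G))

  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        time_h = tp,
                        condition = c("control", "treated"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$sample <- sprintf("%s_t%g_r%d", substr(design$condition, 1, 3),
                           design$time_h, design$replicate)
  design <- design[, c("sample", "condition", "time_h", "replicate")]

  basis <- natural_spline_basis(tp, df = 3)
  B <- basis$basis                       # m x 3, rows follow tp

  intercept <- stats::runif(G, 6, 12)
  b <- matrix(stats::rnorm(G * 3, sd = config$baseline_sd), G, 3)
  n_de <- round(config$prop_de * G)
  de_genes <- if (n_de > 0) sort(sample(genes, n_de)) else character(0)
  gam <- matrix(0, G, 4)                 # offset + 3 shape coefficients
  is_de <- genes %in% de_genes
  gam[is_de, ] <- stats::rnorm(sum(is_de) * 4, sd = config$effect_sd)

  mu_ctrl <- intercept + b %*% t(B)                         # G x m
  delta <- gam[, 1] + gam[, -1, drop = FALSE] %*% t(B)      # G x m
  mu_trt <- mu_ctrl + delta

  sigma2 <- if (is.finite(config$d0)) {
    config$d0 * config$s0_sq / stats::rchisq(G, df = config$d0)
  } else rep(config$s0_sq, G)

  t_idx <- match(design$time_h, tp)
  mu <- matrix(0, G, nrow(design))
  ctrl <- design$condition == "control"
  mu[, ctrl] <- mu_ctrl[, t_idx[ctrl]]
  mu[, !ctrl] <- mu_trt[, t_idx[!ctrl]]
  expr <- mu + matrix(stats::rnorm(G * nrow(design), sd = sqrt(sigma2)),
                      G, nrow(design))
  dimnames(expr) <- list(genes, design$sample)

  list(expr = expr, design = design,
       truth = list(de_genes = de_genes, sigma2 = stats::setNames(sigma2, genes),
                    mu_control = mu_ctrl, mu_treated = mu_trt, basis = basis))
}

# Sample `n_edges` unordered pairs among `n` nodes; when `cap` is finite no
# node exceeds that degree (guarantees strict diagonal dominance downstream).
.sample_edges <- function(n, n_edges, cap = Inf) {
  if (n_edges == 0) return(matrix(integer(0), 0, 2))
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  ord <- sample(nrow(pairs))
  deg <- integer(n)
  keep <- matrix(integer(0), 0, 2)
  for (k in ord) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (deg[i] < cap && deg[j] < cap) {
      keep <- rbind(keep, c(i, j))
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
      if (nrow(keep) == n_edges) break
    }
  }
  keep
}

#' Construct a sparse Gaussian graphical model precision matrix
#'
#' Unit diagonal with `-rho` at the adjacency pattern, so every true edge has
#' partial correlation exactly `rho`. Positive definiteness is checked by
#' eigendecomposition; an infeasible combination of density and magnitude
#' errors with the smallest achieved eigenvalue.
#'
#' @param n_nodes number of nodes.
#' @param edges two-column matrix of node index pairs.
#' @param rho absolute partial correlation on true edges.
#' @return The precision matrix (symmetric, positive definite).
#' @export
ggm_precision <- function(n_nodes, edges, rho) {
  omega <- diag(n_nodes)
  if (nrow(edges) > 0) {
    omega[edges] <- -rho
    omega[edges[, c(2, 1), drop = FALSE]] <- -rho
  }
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8)
    stop(sprintf(paste0("requested partial-correlation magnitude %.3g is ",
                        "infeasible for this graph: smallest achievable ",
                        "eigenvalue %.3g"), rho, min(ev)))
  omega
}

#' Simulate multivariate-normal samples from a sparse gene association network
#'
#' Draws independent samples (by default one per time point x replicate) from
#' the Gaussian graphical model implied by a random sparse graph whose edges
#' carry partial correlations of magnitude `pcor_magnitude`. Random graphs are
#' drawn under a per-node degree cap `floor((1 - eps)/rho)` so the unit-diagonal
#' precision matrix is strictly diagonally dominant, hence positive definite;
#' explicit edge lists bypass the cap but are eigenvalue-checked.
#'
#' @param config a [sim_config()].
#' @param n_samples number of independent samples; default
#'   `length(timepoints) * n_replicates`.
#' @param edges optional explicit two-column matrix of node index pairs.
#' @return A list with `expr` (genes x samples), `truth` (list with
#'   `true_edges` data frame, theoretical partial correlation matrix `pcor`,
#'   covariance `sigma`).
#' @export
gen_network_timeseries <- function(config, n_samples = NULL, edges = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + .seed_offsets[["network"]])
  n <- config$network_n_nodes
  rho <- config$pcor_magnitude
  if (is.null(n_samples))
    n_samples <- length(config$timepoints) * config$n_replicates
  if (is.null(edges)) {
    cap <- max(1L, floor((1 - 1e-8) / rho))
    if (2 * config$network_n_edges > n * cap) cap <- Inf  # fall back, eig-checked
    edges <- .sample_edges(n, config$network_n_edges, cap)
    if (nrow(edges) < config$network_n_edges)
      stop("could not place the requested number of edges under the degree cap")
  } else {
    edges <- as.matrix(edges)
  }
  omega <- ggm_precision(n, edges, rho)
  sigma <- stats::cov2cor(solve(omega))   # diagonal rescale leaves pcor intact
  genes <- sprintf("n%03d", seq_len(n))
  dimnames(sigma) <- list(genes, genes)
  x <- MASS::mvrnorm(n_samples, mu = rep(0, n), Sigma = sigma)
  expr <- t(x)
  dimnames(expr) <- list(genes, sprintf("s%03d", seq_len(n_samples)))

  pc <- -stats::cov2cor(omega)            # -omega_ij / sqrt(omega_ii omega_jj)
  diag(pc) <- 1
  dimnames(pc) <- list(genes, genes)
  true_edges <- if (nrow(edges)) {
    data.frame(gene_a = genes[pmin(edges[, 1], edges[, 2])],
               gene_b = genes[pmax(edges[, 1], edges[, 2])],
               stringsAsFactors = FALSE)
  } else data.frame(gene_a = character(0), gene_b = character(0))
  list(expr = expr,
       truth = list(true_edges = true_edges, pcor = pc, sigma = sigma))
}

#' Simulate gene-set collections with spiked enrichment
#'
#' Draws random sets from the universe; when `enriched_in` is non-empty,
#' `n_enriched` designated sets are oversampled from it (a fraction
#' `enrich_frac` of each such set), making them detectably over-represented in
#' any query resembling `enriched_in`.
#'
#' @param universe character vector of gene ids.
#' @param n_sets number of random (non-spiked) sets.
#' @param size_range length-2 integer range of set sizes, within
#'   `[1, length(universe)]`.
#' @param enriched_in genes from which enriched sets are oversampled.
#' @param n_enriched number of spiked sets (0 when `enriched_in` is empty).
#' @param enrich_frac fraction of each spiked set drawn from `enriched_in`.
#' @param seed integer seed.
#' @return A list with `collection` (a [gene_set_collection()]) and `truth`
#'   (list with `enriched_sets`).
#' @export
gen_gene_sets <- function(universe, n_sets = 50, size_range = c(20, 200),
                          enriched_in = character(0),
                          n_enriched = if (length(enriched_in)) 5L else 0L,
                          enrich_frac = 0.8, seed = 1L) {
  stopifnot(length(universe) >= 1, length(size_range) == 2)
  if (size_range[1] < 1 || size_range[2] > length(universe) ||
      size_range[1] > size_range[2])
    stop("`size_range` must lie within [1, length(universe)]")
  if (!all(enriched_in %in% universe))
    stop("`enriched_in` must be a subset of the universe")
  set.seed(seed + .seed_offsets[["gene_sets"]])
  sizes <- sample(seq(size_range[1], size_range[2]), n_sets + n_enriched,
                  replace = TRUE)
  sets <- vector("list", n_sets + n_enriched)
  names(sets) <- sprintf("SET_%03d", seq_along(sets))
  enriched_names <- character(0)
  for (k in seq_along(sets)) {
    if (k <= n_enriched) {
      n_in <- min(length(enriched_in), round(enrich_frac * sizes[k]))
      rest <- setdiff(universe, enriched_in)
      sets[[k]] <- c(sample(enriched_in, n_in),
                     sample(rest, min(sizes[k] - n_in, length(rest))))
      enriched_names <- c(enriched_names, names(sets)[k])
    } else {
      sets[[k]] <- sample(universe, sizes[k])
    }
  }
  desc <- stats::setNames(ifelse(names(sets) %in% enriched_names,
                                 "spiked enriched set", "random set"),
                          names(sets))
  list(collection = gene_set_collection(sets, desc),
       truth = list(enriched_sets = enriched_names))
}

#' Simulate a segmented copy-number profile over annotated genes
#'
#' Splits each chromosome into `n_segments` non-overlapping half-open
#' `[start, end)` segments (0-based) covering all gene midpoints and assigns
#' each a call in `{-1, 0, +1}`. The recorded truth is the call of the segment
#' containing each gene midpoint.
#'
#' @param genes data frame with columns `gene`, `chrom`, `midpoint`.
#' @param n_segments segments per chromosome.
#' @param seed integer seed.
#' @param call_prob probabilities of loss/neutral/gain per segment.
#' @return A list with `segments` (chrom, start, end, call) and `truth`
#'   (named per-gene call vector).
#' @export
gen_cna_profile <- function(genes, n_segments = 5, seed = 1L,
                            call_prob = c(0.25, 0.5, 0.25)) {
  stopifnot(all(c("gene", "chrom", "midpoint") %in% names(genes)),
            n_segments >= 1)
  if (any(genes$midpoint < 0)) stop("gene midpoints must be non-negative")
  set.seed(seed + .seed_offsets[["cna"]])
  segs <- list()
  for (chr in unique(genes$chrom)) {
    L <- ceiling(max(genes$midpoint[genes$chrom == chr]) * 1.05) + 1
    breaks <- if (n_segments > 1) sort(sample(seq_len(L - 1), n_segments - 1)) else integer(0)
    start <- c(0, breaks)
    end <- c(breaks, L)
    segs[[chr]] <- data.frame(chrom = chr, start = start, end = end,
                              call = sample(c(-1L, 0L, 1L), n_segments,
                                            replace = TRUE, prob = call_prob),
                              stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, c(segs, list(make.row.names = FALSE)))
  truth <- map_genes_to_calls(genes, segments)
  list(segments = segments,
       truth = stats::setNames(truth$call, truth$gene))
}

#' Simulate clonogenic-assay colony counts under a linear-quadratic model
#'
#' Per dish, `colonies ~ Poisson(cells_seeded * PE_e * exp(-(alpha*D + beta*D^2)))`
#' with a per-experiment plating efficiency `PE_e`.
#'
#' @param alpha,beta linear-quadratic parameters (per Gy, per Gy^2), both >= 0.
#' @param plating_efficiency scalar or per-experiment vector in (0, 1].
#' @param doses radiation doses in Gy (non-negative).
#' @param cells_seeded cells plated per dish; one dish is generated for every
#'   combination of experiment, dose and seeding density.
#' @param n_experiments number of independent experiments.
#' @param seed integer seed.
#' @return Data frame with columns `experiment`, `dose`, `cells_seeded`,
#'   `colonies`.
#' @export
gen_colony_counts <- function(alpha, beta, plating_efficiency,
                              doses = c(0, 1, 2, 4, 6, 8),
                              cells_seeded = c(100, 200, 400),
                              n_experiments = 3, seed = 1L) {
  stopifnot(alpha >= 0, beta >= 0,
            all(plating_efficiency > 0), all(plating_efficiency <= 1))
  if (any(doses < 0)) stop("doses must be non-negative")
  set.seed(seed + .seed_offsets[["colony"]])
  pe <- rep_len(plating_efficiency, n_experiments)
  tab <- expand.grid(cells_seeded = cells_seeded, dose = doses,
                     experiment = sprintf("exp%d", seq_len(n_experiments)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  s <- exp(-(alpha * tab$dose + beta * tab$dose^2))
  mu <- tab$cells_seeded * pe[match(tab$experiment,
                                    sprintf("exp%d", seq_len(n_experiments)))] * s
  tab$colonies <- stats::rpois(nrow(tab), mu)
  tab[, c("experiment", "dose", "cells_seeded", "colonies")]
}
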