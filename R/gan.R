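#' Trapezoid integration weights over a time grid
#'
#' Weights proportional to `(t[k+1] - t[k-1]) / 2` for interior points and to
#' the half-width of the first/last interval at the ends, normalised to sum 1.
#' These weight the unevenly spaced sampling times when gene trajectories are
#' treated as functional data.
#'
#' @param times strictly increasing times, at least 2.
#' @return Numeric weights summing to 1.
#' @export
trapezoid_weights <- function(times) {
  m <- length(times)
  if (m < 2) stop("need at least 2 time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing (no duplicates)")
  w <- numeric(m)
  w[1] <- (times[2] - times[1]) / 2
  w[m] <- (times[m] - times[m - 1]) / 2
  if (m > 2) w[2:(m - 1)] <- (times[3:m] - times[1:(m - 2)]) / 2
  w / sum(w)
}

#' Average replicate trajectories per gene and time point
#'
#' @param expr genes x samples log2 matrix.
#' @param design design data frame.
#' @param condition `"treated"`, `"control"`, or `"difference"` (treated mean
#'   minus control mean per time point).
#' @return genes x timepoints matrix; time points as ordered column names.
#' @export
average_trajectories <- function(expr, design,
                                 condition = c("treated", "control", "difference")) {
  condition <- match.arg(condition)
  design <- .check_design(expr, design)
  tp <- sort(unique(design$time_h))
  grp_mean <- function(cond) {
    sapply(tp, function(t) {
      s <- design$sample[design$condition == cond & design$time_h == t]
      rowMeans(expr[, s, drop = FALSE])
    })
  }
  traj <- switch(condition,
                 treated = grp_mean("treated"),
                 control = grp_mean("control"),
                 difference = grp_mean("treated") - grp_mean("control"))
  traj <- matrix(traj, nrow = nrow(expr),
                 dimnames = list(rownames(expr), paste0("t", tp)))
  attr(traj, "times") <- tp
  traj
}

# Weighted standardisation of an observations x variables matrix.
# h1 = 1/(1 - sum(w^2)) generalises n/(n-1); columns with (near-)zero weighted
# variance are flagged and standardised to zero.
.weighted_standardize <- function(x, w) {
  mu <- colSums(x * w)
  xc <- sweep(x, 2, mu)
  h1 <- 1 / (1 - sum(w^2))
  v <- h1 * colSums(xc^2 * w)
  zero <- v < 1e-14
  v_safe <- ifelse(zero, 1, v)
  list(xs = sweep(xc, 2, sqrt(v_safe), "/"), h1 = h1, var = v, zero = zero)
}

#' Weighted correlation matrix
#'
#' Correlation over observations (rows) with optional observation weights;
#' used both for i.i.d. samples (uniform weights) and for trapezoid-weighted
#' mean trajectories. Variables with zero weighted variance get zero
#' correlations with a warning.
#'
#' @param x observations x variables matrix.
#' @param weights observation weights summing to 1; default uniform.
#' @return Correlation matrix.
#' @export
weighted_correlation <- function(x, weights = NULL) {
  n <- nrow(x)
  if (is.null(weights)) weights <- rep(1 / n, n)
  stopifnot(length(weights) == n, all(weights > 0))
  weights <- weights / sum(weights)
  st <- .weighted_standardize(x, weights)
  r <- st$h1 * crossprod(st$xs * weights, st$xs) / 1  # h1 * sum_k w xs_i xs_j
  if (any(st$zero)) {
    warning(sum(st$zero), " variables with zero weighted variance; ",
            "their correlations are set to 0")
    r[st$zero, ] <- 0; r[, st$zero] <- 0
  }
  diag(r) <- 1
  r <- pmin(pmax(r, -1), 1)
  dimnames(r) <- list(colnames(x), colnames(x))
  r
}

#' Dynamical correlation between gene trajectories
#'
#' Replicate-averaged trajectories are centred by their trapezoid-weighted
#' time mean and correlated under the same weights:
#' `r_ij = sum_k w_k xc_ik xc_jk / sqrt(sum w xc_i^2 * sum w xc_j^2)`.
#'
#' @param traj genes x timepoints matrix (see [average_trajectories()]).
#' @param times time points (hours); default from the `times` attribute.
#' @param weights time weights; default [trapezoid_weights()] of `times`.
#' @return Gene x gene correlation matrix.
#' @export
dynamical_correlation <- function(traj, times = attr(traj, "times"),
                                  weights = NULL) {
  if (is.null(times)) stop("supply `times` or a matrix with a times attribute")
  if (length(times) < 2) stop("need at least 2 time points")
  if (is.null(weights)) weights <- trapezoid_weights(times)
  weighted_correlation(t(traj), weights)
}

#' Shrinkage estimation of the correlation matrix
#'
#' Schaefer-Strimmer shrinkage towards the identity target:
#' `lambda* = sum_{i!=j} Var-hat(r_ij) / sum_{i!=j} r_ij^2`, clipped to
#' `[0, 1]`, and `R* = (1 - lambda*) R + lambda* I`. The variance term is the
#' empirical variance of the standardised cross-products over observations;
#' with observation weights `w` (summing to 1) it is
#' `h1^3 * sum_k w_k^2 (w_kij - wbar_ij)^2` with `h1 = 1/(1 - sum w^2)`,
#' which reduces to the usual `n/(n-1)^3 * sum (w_kij - wbar_ij)^2` for
#' uniform weights.
#'
#' @param x observations x variables data matrix.
#' @param weights optional observation weights.
#' @return List: `R` (shrunken correlation), `lambda`, `r_raw`, `n_obs`.
#' @export
shrink_correlation <- function(x, weights = NULL) {
  n <- nrow(x)
  if (n < 3) stop("need at least 3 effective observations")
  if (is.null(weights)) weights <- rep(1 / n, n)
  weights <- weights / sum(weights)
  st <- .weighted_standardize(x, weights)
  xs <- st$xs
  h1 <- st$h1
  r <- st$h1 * crossprod(xs * weights, xs)
  diag(r) <- 1
  p <- ncol(x)
  # var-hat(r_ij) via sums over observations, vectorised:
  # sum_k w_k^2 (w_kij - wbar_ij)^2
  #   = sum_k w_k^2 w_kij^2 - 2 wbar_ij sum_k w_k^2 w_kij + wbar_ij^2 sum w_k^2
  # with w_kij = xs_ki xs_kj and wbar_ij = sum_k w_k w_kij = r_ij / h1
  xs2 <- xs^2
  S2 <- crossprod(xs2 * weights^2, xs2)          # sum w^2 w_kij^2
  Sw <- crossprod(xs * weights^2, xs)            # sum w^2 w_kij
  wbar <- r / h1
  varhat <- h1^3 * (S2 - 2 * wbar * Sw + wbar^2 * sum(weights^2))
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  lambda <- if (denom <= 0) 1 else min(max(sum(varhat[off]) / denom, 0), 1)
  R <- (1 - lambda) * r
  diag(R) <- 1
  dimnames(R) <- list(colnames(x), colnames(x))
  list(R = R, lambda = lambda, r_raw = r, n_obs = n)
}

#' Partial correlations from a (shrunken) correlation matrix
#'
#' Inverts the correlation matrix and standardises:
#' `p_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj)`; the diagonal is set to 1 by
#' convention and excluded from edge tests.
#'
#' @param R positive-definite correlation matrix (shrinkage with
#'   `lambda > 0` and identity target guarantees this).
#' @return Symmetric partial-correlation matrix.
#' @export
partial_correlations <- function(R) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  omega <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix is singular; apply shrinkage (lambda > 0) first"))
  p <- -omega / sqrt(outer(diag(omega), diag(omega)))
  diag(p) <- 1
  p <- (p + t(p)) / 2
  dimnames(p) <- dimnames(R)
  p
}

# null density of sample partial correlations under kappa effective df:
# f0(p; kappa) = (1 - p^2)^((kappa-3)/2) * Gamma(kappa/2) /
#                (sqrt(pi) * Gamma((kappa-1)/2))
.pcor_null_density <- function(p, kappa) {
  exp((kappa - 3) / 2 * log1p(-p^2) +
        lgamma(kappa / 2) - 0.5 * log(pi) - lgamma((kappa - 1) / 2))
}

#' Fit the two-component mixture model for edge posterior probabilities
#'
#' Models the off-diagonal partial correlations as
#' `f(p) = eta0 * f0(p; kappa) + (1 - eta0) * fA(p)` with the null density of
#' sample partial correlations at `kappa` effective degrees of freedom and a
#' uniform alternative on `[-1, 1]`. `(eta0, kappa)` are fitted by maximum
#' likelihood; the per-edge posterior probability of a true association is
#' `prob = (1 - eta0) * fA(p) / f(p)` (one minus the local false discovery
#' rate), monotone non-decreasing in `|p|`.
#'
#' @param P partial-correlation matrix (or a numeric vector of partial
#'   correlations).
#' @return Object of class `edge_posterior_model`: `eta0`, `kappa`, `loglik`,
#'   `n`, `convergence`.
#' @export
fit_edge_posteriors <- function(P) {
  p <- if (is.matrix(P)) P[upper.tri(P)] else as.numeric(P)
  if (length(p) < 100)
    warning("fewer than 100 partial correlations; mixture fit may be unstable")
  p <- pmin(pmax(p, -1 + 1e-12), 1 - 1e-12)
  nll <- function(par) {
    eta0 <- stats::plogis(par[1])
    kappa <- 3 + exp(par[2])
    -sum(log(eta0 * .pcor_null_density(p, kappa) + (1 - eta0) * 0.5))
  }
  kap0 <- max(4, min(1 / max(stats::var(p), 1e-6), 1e5))
  init <- c(stats::qlogis(0.9), log(kap0 - 3))
  opt <- stats::optim(init, nll, method = "L-BFGS-B",
                      lower = c(-5, log(0.5)), upper = c(10, log(2e5)))
  if (!opt$convergence %in% c(0L, 52L))
    stop("edge-posterior mixture fit did not converge (optim code ",
         opt$convergence, "): ", opt$message)
  structure(list(eta0 = stats::plogis(opt$par[1]),
                 kappa = 3 + exp(opt$par[2]),
                 loglik = -opt$value, n = length(p),
                 convergence = opt$convergence),
            class = "edge_posterior_model")
}

#' Posterior probability of a true edge for given partial correlations
#' @param model an `edge_posterior_model`.
#' @param p partial correlations.
#' @return Posterior probabilities in `[0, 1]` (even in `p`).
#' @export
edge_posterior <- function(model, p) {
  stopifnot(inherits(model, "edge_posterior_model"))
  fa <- (1 - model$eta0) * 0.5
  fa / (model$eta0 * .pcor_null_density(p, model$kappa) + fa)
}

#' Assemble the gene association network at a posterior threshold
#'
#' @param P partial-correlation matrix with gene dimnames.
#' @param model fitted [fit_edge_posteriors()] model.
#' @param threshold minimum posterior probability for an edge (closed, i.e.
#'   `prob >= threshold`; ties included). Default 0.95.
#' @return Object of class `gene_network`: `nodes` (all genes tested,
#'   isolated ones retained), `edges` (data frame gene_a, gene_b, pcor, prob).
#' @export
build_network <- function(P, model, threshold = 0.95) {
  genes <- rownames(P)
  if (is.null(genes)) genes <- sprintf("v%d", seq_len(nrow(P)))
  idx <- which(upper.tri(P), arr.ind = TRUE)
  pc <- P[upper.tri(P)]
  prob <- edge_posterior(model, pc)
  keep <- prob >= threshold
  edges <- data.frame(gene_a = genes[idx[keep, 1]],
                      gene_b = genes[idx[keep, 2]],
                      pcor = pc[keep], prob = prob[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = genes, edges = edges, threshold = threshold,
                 model = model),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  deg <- table(factor(c(x$edges$gene_a, x$edges$gene_b), levels = x$nodes))
  cat(sprintf("Gene association network: %d nodes (%d connected), %d edges at prob >= %.2f\n",
              length(x$nodes), sum(deg > 0), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Convert a gene network to an igraph object
#' @param network a `gene_network`.
#' @return An undirected igraph graph including isolated nodes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  igraph::graph_from_data_frame(network$edges[, c("gene_a", "gene_b")],
                                directed = FALSE,
                                vertices = data.frame(name = network$nodes))
}

#' First neighborhood of a focal gene
#'
#' The focal gene, its adjacent nodes, and all edges among that node set (the
#' induced subgraph on the closed neighborhood).
#'
#' @param network a `gene_network`.
#' @param gene focal gene id.
#' @return A `gene_network` restricted to the closed neighborhood.
#' @export
first_neighborhood <- function(network, gene) {
  stopifnot(inherits(network, "gene_network"))
  if (!gene %in% network$nodes) stop("unknown gene: ", gene)
  e <- network$edges
  nb <- union(e$gene_b[e$gene_a == gene], e$gene_a[e$gene_b == gene])
  nodes <- sort(union(gene, nb))
  sub <- e[e$gene_a %in% nodes & e$gene_b %in% nodes, , drop = FALSE]
  rownames(sub) <- NULL
  structure(list(nodes = nodes, edges = sub, threshold = network$threshold,
                 model = network$model, focal = gene),
            class = "gene_network")
}

#' Reconstruct a gene association network from observation data
#'
#' Chains [shrink_correlation()], [partial_correlations()],
#' [fit_edge_posteriors()] and [build_network()].
#'
#' @param x observations x genes matrix (i.i.d. samples, or weighted
#'   trajectories via `weights`).
#' @param weights optional observation weights (e.g. trapezoid time weights).
#' @param threshold posterior edge threshold, default 0.95.
#' @return List: `network`, `pcor` matrix, `lambda`, `model`.
#' @export
reconstruct_network <- function(x, weights = NULL, threshold = 0.95) {
  sh <- shrink_correlation(x, weights)
  P <- partial_correlations(sh$R)
  model <- fit_edge_posteriors(P)
  list(network = build_network(P, model, threshold),
       pcor = P, lambda = sh$lambda, model = model)
}

#' Build a gene association network from a time-course experiment
#'
#' Averages replicates per time point for the chosen condition over the given
#' (typically temporally differentially expressed) genes, applies trapezoid
#' time weights, and reconstructs the network.
#'
#' @param expr genes x samples log2 matrix.
#' @param design design data frame.
#' @param genes genes to include (default all).
#' @param condition which trajectories feed the network: `"treated"`
#'   (default), `"control"`, or `"difference"`.
#' @param threshold posterior edge threshold, default 0.95.
#' @return As [reconstruct_network()].
#' @export
build_gan <- function(expr, design, genes = rownames(expr),
                      condition = "treated", threshold = 0.95) {
  traj <- average_trajectories(expr[genes, , drop = FALSE], design, condition)
  tp <- attr(traj, "times")
  reconstruct_network(t(traj), weights = trapezoid_weights(tp),
                      threshold = threshold)
}

#' Mann-Whitney AUC of a score against a binary truth
#'
#' Rank-based area under the ROC curve: the probability that a randomly chosen
#' positive outranks a randomly chosen negative.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param truth logical vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
ranking_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth), is.logical(truth))
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("need both positive and negative cases")
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
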