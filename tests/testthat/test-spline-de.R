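design_times <- c(0.25, 2, 7, 12, 24, 48, 72, 96)

make_sim <- function(...) gen_timecourse(sim_config(...))

test_that("natural spline basis has the required rank and natural tails", {
  b <- natural_spline_basis(design_times, df = 3)
  expect_equal(dim(b$basis), c(8, 3))
  expect_equal(qr(cbind(1, b$basis))$rank, 4)
  expect_error(natural_spline_basis(c(1, 2, 3), df = 3), "distinct times")

  # beyond the boundary knots a natural spline is linear: second differences
  # vanish there
  for (x0 in c(b$boundary[1] - 1, b$boundary[2] + 1)) {
    h <- 1e-3
    B <- eval_spline_basis(b, c(x0 - h, x0, x0 + h))
    d2 <- (B[1, ] - 2 * B[2, ] + B[3, ]) / h^2
    expect_true(all(abs(d2) < 1e-6))
  }
})

test_that("spline basis spans the truncated-power natural spline space", {
  b <- natural_spline_basis(design_times, df = 3)
  all_knots <- sort(c(b$boundary, b$knots))
  X_ns <- cbind(1, b$basis)
  X_tp <- natural_tp_basis(design_times, all_knots)
  expect_equal(hat_matrix(X_ns), hat_matrix(X_tp), tolerance = 1e-8)
})

test_that("gene-wise spline fits match the normal-equation oracle", {
  tp <- c(1, 4, 9, 16)
  design <- expand.grid(replicate = 1:2, time_h = tp,
                        condition = c("control", "treated"),
                        stringsAsFactors = FALSE)
  design$sample <- sprintf("%s_t%d_r%d", design$condition, design$time_h,
                           design$replicate)
  set.seed(42)
  expr <- matrix(rnorm(2 * nrow(design), sd = 1), 2, nrow(design),
                 dimnames = list(c("gA", "gB"), design$sample))
  fits <- fit_spline_model(expr, design)
  B <- eval_spline_basis(fits$basis, design$time_h)
  x <- as.numeric(design$condition == "treated")
  X <- cbind(1, B, x, x * B)
  for (g in 1:2) {
    beta_hat <- solve(crossprod(X), crossprod(X, expr[g, ]))
    expect_equal(unname(fits$coef[g, ]), unname(drop(beta_hat)),
                 tolerance = 1e-10)
    expect_equal(unname(fits$rss1[g]),
                 sum((expr[g, ] - X %*% beta_hat)^2), tolerance = 1e-10)
  }
})

test_that("degenerate genes produce the forced coefficient patterns", {
  sim <- make_sim(n_genes = 3, prop_de = 0, seed = 1)
  expr <- sim$expr
  # gene 1: identical values in both conditions (same value per time point)
  tpi <- match(sim$design$time_h, sort(unique(sim$design$time_h)))
  expr[1, ] <- (1:8)[tpi]
  # gene 2: treated = control + 1
  expr[2, ] <- (1:8)[tpi] + (sim$design$condition == "treated")
  fits <- fit_spline_model(expr, sim$design)
  gam_cols <- grep("^gamma", colnames(fits$coef))
  expect_equal(unname(fits$coef[1, gam_cols]), rep(0, 4), tolerance = 1e-10)
  expect_equal(fits$rss0[1], fits$rss1[1], tolerance = 1e-10)
  expect_equal(unname(fits$coef[2, gam_cols]), c(1, 0, 0, 0), tolerance = 1e-8)
})

test_that("degenerate designs are rejected", {
  sim <- make_sim(n_genes = 2, seed = 1)
  design <- sim$design
  design$condition <- "control"   # no treated samples at all
  expect_error(fit_spline_model(sim$expr, design), "conditions")
  keep <- sim$design$time_h %in% c(0.25, 2, 7)  # fewer times than df + 1
  expect_error(fit_spline_model(sim$expr[, sim$design$sample[keep]],
                                sim$design[keep, ]),
               "distinct times")
})

test_that("moderated F reduces to its limits and is calibrated under the null", {
  sim <- make_sim(n_genes = 300, prop_de = 0, seed = 11)
  fits <- fit_spline_model(sim$expr, sim$design)

  # d0 = 0: ordinary per-gene F
  tab0 <- moderated_f_test(fits, d0 = 0)
  F_ord <- ((fits$rss0 - fits$rss1) / fits$q) / (fits$rss1 / fits$df_resid)
  p_ord <- stats::pf(F_ord, fits$q, fits$df_resid, lower.tail = FALSE)
  expect_equal(tab0$F, unname(F_ord), tolerance = 1e-10)
  expect_equal(tab0$p, unname(p_ord), tolerance = 1e-10)

  # d0 = Inf: fully pooled denominator
  tabI <- moderated_f_test(fits, d0 = Inf, s0_sq = 0.05)
  expect_equal(tabI$F, unname((fits$rss0 - fits$rss1) / fits$q / 0.05),
               tolerance = 1e-10)

  # estimated prior: null p-values roughly uniform
  tab <- moderated_f_test(fits)
  expect_gt(stats::ks.test(tab$p, "punif")$p.value, 0.01)
})

test_that("null p-value fraction matches the nominal level at seed 11", {
  sim <- make_sim(n_genes = 1000, prop_de = 0, seed = 11)
  de <- timecourse_de(sim$expr, sim$design)
  expect_lt(abs(mean(de$table$p < 0.05) - 0.05), 0.014)
})

test_that("timecourse_de is invariant to column permutation and gene offsets", {
  sim <- make_sim(n_genes = 60, prop_de = 0.3, seed = 21)
  de <- timecourse_de(sim$expr, sim$design)
  perm <- sample(ncol(sim$expr))
  de_p <- timecourse_de(sim$expr[, perm], sim$design)
  expect_equal(de$table$p, de_p$table$p, tolerance = 1e-12)
  shifted <- sim$expr + 5
  de_s <- timecourse_de(shifted, sim$design)
  expect_equal(de$table$F, de_s$table$F, tolerance = 1e-9)
})

test_that("single-gene input gives fdr equal to p", {
  p <- 0.03
  expect_equal(benjamini_hochberg(p), 0.03)
  sim <- make_sim(n_genes = 60, seed = 5)
  suppressWarnings({
    de1 <- timecourse_de(sim$expr[1, , drop = FALSE], sim$design, d0 = 0)
  })
  expect_equal(de1$table$fdr, de1$table$p)
})

test_that("static DE applies strict thresholds on both axes", {
  set.seed(31)
  G <- 200
  base <- matrix(rnorm(G * 6, mean = 8, sd = 0.05), G, 6,
                 dimnames = list(sprintf("g%03d", 1:G), paste0("a", 1:6)))
  trt <- base + rnorm(G * 6, sd = 0.05)
  colnames(trt) <- paste0("b", 1:6)
  # gene 1: log2FC exactly 0.5 -> NOT flagged; gene 2: large shift -> flagged
  trt[1, ] <- base[1, ] + 0.5
  trt[2, ] <- base[2, ] + log2(16.417)
  trt[3, ] <- base[3, ] + log2(0.263)
  tab <- static_de(base, trt)
  expect_false(tab$de[1])
  expect_true(tab$de[2]); expect_equal(tab$FC[2], 16.417, tolerance = 0.02)
  expect_true(tab$de[3]); expect_equal(tab$direction[3], "down")

  same <- static_de(base, base + matrix(rnorm(G * 6, sd = 1e-3), G, 6))
  expect_false(any(same$de))
  expect_error(static_de(base[, 1, drop = FALSE], trt), "at least 2 samples")
})

test_that("early/late classification follows the strict fold-change windows", {
  cfg <- sim_config(n_genes = 3, prop_de = 0, seed = 2)
  sim <- gen_timecourse(cfg)
  expr <- sim$expr; design <- sim$design
  tp <- sort(unique(design$time_h))
  base <- 8
  expr[] <- base
  set_fc <- function(expr, gene, t, fc) {
    s <- design$sample[design$condition == "treated" & design$time_h == t]
    expr[gene, s] <- base + log2(fc); expr
  }
  expr <- set_fc(expr, 1, 7, 2.5)     # early only
  expr <- set_fc(expr, 2, 72, 0.4)    # late only
  for (t in tp) expr <- set_fc(expr, 3, t, 2.0)  # boundary: never crosses
  cls <- classify_early_late(expr, design, rownames(expr))$class
  expect_equal(cls$early, c(TRUE, FALSE, FALSE))
  expect_equal(cls$late, c(FALSE, TRUE, FALSE))
  expect_error(classify_early_late(expr, design, "nope"), "absent")
})

test_that("early/late depends only on per-time-point group means", {
  sim <- make_sim(n_genes = 30, prop_de = 0.5, seed = 13)
  de_genes <- rownames(sim$expr)[1:10]
  cls <- classify_early_late(sim$expr, sim$design, de_genes)
  # permute replicates within each condition x time cell
  design2 <- sim$design
  for (cond in c("control", "treated")) for (t in unique(design2$time_h)) {
    i <- which(design2$condition == cond & design2$time_h == t)
    design2$sample[i] <- sample(design2$sample[i])
  }
  expr2 <- sim$expr[, design2$sample]
  colnames(expr2) <- design2$sample
  cls2 <- classify_early_late(sim$expr, design2, de_genes)
  expect_equal(cls$class, cls2$class)
  expect_equal(cls$fc, cls2$fc, tolerance = 1e-12)
})

test_that("Benjamini-Hochberg matches the hand-computed step-up values", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  p <- c(0.001, 0.8, 0.04, 0.2, 0.3)
  expect_true(all(benjamini_hochberg(p) >= p))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(benjamini_hochberg(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("variance-prior estimation matches limma's moment estimator", {
  skip_if_not_installed("limma")
  set.seed(77)
  d0_true <- 5; s0 <- 0.1; dg <- 8
  s2 <- s0 * d0_true / rchisq(2000, d0_true) * rchisq(2000, dg) / dg
  ours <- fit_variance_prior(s2, dg)
  ref <- limma::fitFDist(s2, df1 = dg)
  expect_equal(ours$d0, ref$df2, tolerance = 1e-6)
  expect_equal(ours$s0_sq, ref$scale, tolerance = 1e-6)
})
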