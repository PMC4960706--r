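#' Natural cubic spline basis over design times
#'
#' Builds a `df`-column natural cubic spline basis (zero second derivative
#' beyond the boundary knots) with boundary knots at the minimum and maximum
#' design time and interior knots at quantiles of the distinct times.
#'
#' @param times numeric times (hours); at least `df + 1` distinct values.
#' @param df spline degrees of freedom (number of basis columns), default 3.
#' @return An object of class `spline_basis`: list with `times`, `df`,
#'   `basis` (length(times) x df matrix), `knots`, `boundary`.
#' @export
natural_spline_basis <- function(times, df = 3) {
  u <- sort(unique(times))
  if (length(u) < df + 1)
    stop(sprintf("need at least %d distinct times for a %d-df natural spline",
                 df + 1, df))
  probs <- seq(0, 1, length.out = df + 1)[-c(1, df + 1)]
  knots <- unname(stats::quantile(u, probs = probs))
  B <- splines::ns(times, knots = knots, Boundary.knots = range(u))
  structure(list(times = times, df = df,
                 basis = matrix(as.numeric(B), nrow = length(times),
                                dimnames = list(NULL, paste0("B", seq_len(df)))),
                 knots = knots, boundary = range(u)),
            class = "spline_basis")
}

#' Evaluate a fitted spline basis at new times
#' @param basis a [natural_spline_basis()] object.
#' @param times numeric times.
#' @return A matrix with `basis$df` columns.
#' @export
eval_spline_basis <- function(basis, times) {
  stopifnot(inherits(basis, "spline_basis"))
  B <- splines::ns(times, knots = basis$knots, Boundary.knots = basis$boundary)
  matrix(as.numeric(B), nrow = length(times),
         dimnames = list(NULL, paste0("B", seq_len(basis$df))))
}

.check_design <- function(expr, design) {
  req <- c("sample", "condition", "time_h", "replicate")
  if (!all(req %in% names(design)))
    stop("design must have columns sample, condition, time_h, replicate")
  if (!setequal(colnames(expr), design$sample))
    stop("expression columns and design samples do not match")
  if (anyNA(expr)) stop("expression matrix contains missing values")
  if (!all(design$condition %in% c("control", "treated")))
    stop("condition must be 'control' or 'treated'")
  tc <- sort(unique(design$time_h[design$condition == "control"]))
  tt <- sort(unique(design$time_h[design$condition == "treated"]))
  if (!identical(tc, tt))
    stop("both conditions must share the identical set of time points")
  design[match(colnames(expr), design$sample), , drop = FALSE]
}

#' Fit the gene-wise spline time-course model
#'
#' Per gene, ordinary least squares of log2 expression on
#' `[1, B1..BK, x, x*B1..x*BK]` where `x` indicates the treated condition: the
#' baseline coefficients describe the shared time course and the treatment
#' coefficients (`gamma`) the condition difference. The null model omits the
#' gamma block (or, for a shape-only test, retains the offset).
#'
#' @param expr genes x samples log2 matrix.
#' @param design design data frame (see [sim_config()] output).
#' @param basis optional [natural_spline_basis()]; built from the design times
#'   when `NULL`.
#' @param null_includes_offset if `TRUE` the null model keeps the treatment
#'   offset so only the shape coefficients are tested (`q = df` instead of
#'   `df + 1`).
#' @return List with per-gene `coef` (full-model coefficients), `rss0`,
#'   `rss1`, `df_resid`, `q`, `sigma2`, plus the design and basis used.
#' @export
fit_spline_model <- function(expr, design, basis = NULL,
                             null_includes_offset = FALSE) {
  design <- .check_design(expr, design)
  if (is.null(basis)) basis <- natural_spline_basis(sort(unique(design$time_h)))
  B <- eval_spline_basis(basis, design$time_h)
  x <- as.numeric(design$condition == "treated")
  X1 <- cbind(intercept = 1, B, trt = x, x * B)
  colnames(X1) <- c("intercept", paste0("B", seq_len(basis$df)),
                    "gamma0", paste0("gamma", seq_len(basis$df)))
  null_cols <- c("intercept", paste0("B", seq_len(basis$df)),
                 if (null_includes_offset) "gamma0")
  X0 <- X1[, null_cols, drop = FALSE]

  qr1 <- qr(X1)
  if (qr1$rank < ncol(X1)) {
    bad <- colnames(X1)[-seq_len(qr1$rank)]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  Y <- t(expr)
  cf <- qr.coef(qr1, Y)
  rss1 <- colSums(qr.resid(qr1, Y)^2)
  rss0 <- colSums(qr.resid(qr(X0), Y)^2)
  df_resid <- nrow(Y) - ncol(X1)
  list(genes = rownames(expr), coef = t(cf),
       rss0 = rss0, rss1 = rss1,
       df_resid = rep(df_resid, ncol(Y)),
       q = ncol(X1) - ncol(X0),
       sigma2 = rss1 / df_resid,
       design = design, basis = basis)
}

#' Invert the trigamma function
#'
#' Newton iteration solving `trigamma(y) = x`; used by the moment-based
#' estimator of the variance-prior degrees of freedom.
#'
#' @param x positive values.
#' @return `y` with `trigamma(y) = x`.
#' @export
trigamma_inverse <- function(x) {
  stopifnot(all(x > 0))
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Estimate the gene-variance prior by moment matching
#'
#' Fits the scaled-F hierarchical model for gene-wise sample variances: on the
#' log scale, `e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2)` has mean
#' `log s0^2 + digamma(d0/2) - log(d0/2)` and excess variance
#' `trigamma(d0/2)`; `d0` is obtained by inverting the trigamma function and
#' `s0^2` from the mean. When the observed variance of `e` does not exceed the
#' sampling term, `d0 = Inf` and all gene variances pool to `s0^2`.
#'
#' @param s2 gene-wise residual variances.
#' @param df residual degrees of freedom (scalar or per-gene).
#' @return List with `d0` and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- df > 0 & is.finite(s2)
  if (any(!ok)) warning(sum(!ok), " genes with zero residual df excluded from ",
                        "hyperparameter estimation")
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 50)
    warning("fewer than 50 genes: variance-prior estimates may be unstable")
  s2 <- pmax(s2, 1e-300)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1)
  excess <- evar - mean(trigamma(df / 2))
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0)
}

#' Empirical-Bayes moderated F-test for the spline time-course model
#'
#' Shrinks gene-wise variances towards the estimated prior,
#' `s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and tests the treatment
#' coefficient block with `F = ((RSS0 - RSS1)/q) / s_tilde^2` on
#' `(q, d0 + d_g)` degrees of freedom, followed by Benjamini-Hochberg
#' adjustment across genes.
#'
#' @param fits output of [fit_spline_model()].
#' @param d0 optional forced prior degrees of freedom: `0` gives the ordinary
#'   per-gene F-test, `Inf` full pooling to `s0_sq`; `NULL` (default)
#'   estimates it from the data.
#' @param s0_sq optional forced prior variance scale (used with forced `d0`).
#' @return Data frame (one row per gene): `gene`, `F`, `p`, `fdr`, the fitted
#'   coefficients, `sigma2`, `df_resid`; prior stored in attributes
#'   `d0`, `s0_sq`.
#' @export
moderated_f_test <- function(fits, d0 = NULL, s0_sq = NULL) {
  s2 <- fits$sigma2
  dg <- fits$df_resid
  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, dg)
    d0 <- prior$d0; s0_sq <- prior$s0_sq
  } else if (is.null(s0_sq)) {
    s0_sq <- if (d0 > 0) fit_variance_prior(s2, dg)$s0_sq else 0
  }
  s_tilde <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + dg * s2) / (d0 + dg)
  Fstat <- ((fits$rss0 - fits$rss1) / fits$q) / s_tilde
  p <- stats::pf(Fstat, fits$q, d0 + dg, lower.tail = FALSE)
  out <- data.frame(gene = fits$genes, F = Fstat, p = p,
                    fdr = benjamini_hochberg(p),
                    sigma2 = s2, df_resid = dg,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- cbind(out, as.data.frame(fits$coef))
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Time-course differential expression between treated and control
#'
#' Composition of [natural_spline_basis()], [fit_spline_model()] and
#' [moderated_f_test()]: genes whose treated time course differs from control
#' under the 3-df natural cubic spline model at the given FDR are flagged as
#' temporally differentially expressed.
#'
#' @param expr genes x samples log2 matrix.
#' @param design design data frame.
#' @param fdr_threshold adjusted-p cutoff, default 0.05.
#' @param df spline degrees of freedom, default 3.
#' @param d0,s0_sq optional forced variance prior (see [moderated_f_test()]).
#' @param test `"all"` tests offset plus shape coefficients jointly
#'   (`q = df + 1`); `"shape"` tests the shape coefficients only.
#' @return List with `table` (statistics for all genes) and `de_genes`
#'   (character vector with `fdr < fdr_threshold`).
#' @export
timecourse_de <- function(expr, design, fdr_threshold = 0.05, df = 3,
                          d0 = NULL, s0_sq = NULL,
                          test = c("all", "shape")) {
  test <- match.arg(test)
  design <- .check_design(expr, design)
  basis <- natural_spline_basis(sort(unique(design$time_h)), df = df)
  fits <- fit_spline_model(expr, design, basis,
                           null_includes_offset = (test == "shape"))
  tab <- moderated_f_test(fits, d0 = d0, s0_sq = s0_sq)
  list(table = tab, de_genes = tab$gene[tab$fdr < fdr_threshold],
       basis = basis)
}

#' Static (single time point / status quo) differential expression
#'
#' Moderated t-test on the mean log2 difference between two sample groups over
#' the same genes, with the empirical-Bayes variance squeeze used by the
#' time-course test. A gene is flagged differentially expressed iff its
#' absolute log2 fold change strictly exceeds `lfc_threshold` AND its FDR is
#' strictly below `fdr_threshold`.
#'
#' @param exprA,exprB genes x samples log2 matrices for the two groups
#'   (identical gene sets; `logFC` is B minus A).
#' @param lfc_threshold minimum absolute log2 fold change, default 0.5.
#' @param fdr_threshold FDR cutoff, default 0.05.
#' @return Data frame: `gene`, `logFC`, `FC` (linear scale), `t`, `p`, `fdr`,
#'   `de` (logical flag), `direction`.
#' @export
static_de <- function(exprA, exprB, lfc_threshold = 0.5, fdr_threshold = 0.05) {
  if (!identical(rownames(exprA), rownames(exprB)))
    stop("both groups must cover the same genes in the same order")
  nA <- ncol(exprA); nB <- ncol(exprB)
  if (nA < 2 || nB < 2)
    stop("need at least 2 samples per group to estimate variances")
  mA <- rowMeans(exprA); mB <- rowMeans(exprB)
  lfc <- mB - mA
  ssA <- rowSums((exprA - mA)^2)
  ssB <- rowSums((exprB - mB)^2)
  dg <- nA + nB - 2
  s2 <- (ssA + ssB) / dg
  prior <- fit_variance_prior(s2, dg)
  s_tilde <- if (is.infinite(prior$d0)) rep(prior$s0_sq, length(s2)) else
    (prior$d0 * prior$s0_sq + dg * s2) / (prior$d0 + dg)
  tstat <- lfc / sqrt(s_tilde * (1 / nA + 1 / nB))
  p <- 2 * stats::pt(abs(tstat), prior$d0 + dg, lower.tail = FALSE)
  fdr <- benjamini_hochberg(p)
  de <- abs(lfc) > lfc_threshold & fdr < fdr_threshold
  data.frame(gene = rownames(exprA), logFC = lfc, FC = 2^lfc,
             t = tstat, p = p, fdr = fdr, de = de,
             direction = ifelse(lfc > 0, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify early and late radiation-responding genes
#'
#' Per-time-point fold change `FC(t) = 2^(mean treated log2 - mean control
#' log2)` over replicates. A differentially expressed gene is an early
#' responder iff `FC(t) > fc_hi` or `FC(t) < fc_lo` at any time within the
#' first day (`t <= day1_max`), and a late responder iff the same holds at any
#' time in `(day1_max, late_max]`. Both thresholds are strict; the flags are
#' not mutually exclusive.
#'
#' @param expr genes x samples log2 matrix.
#' @param design design data frame.
#' @param de_genes genes to classify (must be present in `expr`).
#' @param fc_hi,fc_lo fold-change windows, defaults 2.0 and 0.5.
#' @param day1_max end of the early window in hours (default 24; the 24 h
#'   sample counts as day 1).
#' @param late_max end of the late window in hours, default 96.
#' @return List with `class` (data frame gene/early/late) and `fc`
#'   (genes x time points fold-change matrix, linear scale).
#' @export
classify_early_late <- function(expr, design, de_genes,
                                fc_hi = 2.0, fc_lo = 0.5,
                                day1_max = 24, late_max = 96) {
  design <- .check_design(expr, design)
  missing <- setdiff(de_genes, rownames(expr))
  if (length(missing))
    stop("genes absent from the expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  tp <- sort(unique(design$time_h))
  if (length(de_genes) == 0) {
    return(list(class = data.frame(gene = character(0), early = logical(0),
                                   late = logical(0), stringsAsFactors = FALSE),
                fc = matrix(numeric(0), 0, length(tp),
                            dimnames = list(NULL, paste0("t", tp)))))
  }
  fc <- sapply(tp, function(t) {
    trt <- design$sample[design$condition == "treated" & design$time_h == t]
    ctl <- design$sample[design$condition == "control" & design$time_h == t]
    2^(rowMeans(expr[de_genes, trt, drop = FALSE]) -
         rowMeans(expr[de_genes, ctl, drop = FALSE]))
  })
  fc <- matrix(fc, nrow = length(de_genes),
               dimnames = list(de_genes, paste0("t", tp)))
  hit <- fc > fc_hi | fc < fc_lo
  early_cols <- tp <= day1_max
  late_cols <- tp > day1_max & tp <= late_max
  cls <- data.frame(gene = de_genes,
                    early = rowSums(hit[, early_cols, drop = FALSE]) > 0,
                    late = rowSums(hit[, late_cols, drop = FALSE]) > 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(class = cls, fc = fc)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with enforced monotonicity, order-preserving with the
#' input vector.
#'
#' @param pvalues numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(pvalues, method = "BH")
}
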