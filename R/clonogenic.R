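#' Poisson log-likelihood machinery for the linear-quadratic model
#'
#' The surviving fraction after dose D is `S(D) = exp(-(alpha*D + beta*D^2))`
#' and each dish contributes `colonies ~ Poisson(cells_seeded * PE_e * S(D))`
#' with a per-experiment plating efficiency `PE_e`. For fixed (alpha, beta)
#' the ML plating efficiencies have the closed form
#' `PE_e = sum(colonies) / sum(cells * S)` within each experiment, so the
#' optimisation runs over (alpha, beta) only with the PEs profiled out.
#' @noRd
.lq_profile <- function(par, counts) {
  s <- exp(-(par[1] * counts$dose + par[2] * counts$dose^2))
  base <- counts$cells_seeded * s
  pe <- tapply(counts$colonies, counts$experiment, sum) /
    tapply(base, counts$experiment, sum)
  pe <- stats::setNames(as.numeric(pe), names(pe))
  mu <- base * pe[counts$experiment]
  k <- counts$colonies
  ll <- sum(ifelse(k > 0, k * log(mu), 0) - mu)
  list(loglik = ll, pe = pe, mu = mu)
}

.lq_validate <- function(counts) {
  req <- c("experiment", "dose", "cells_seeded", "colonies")
  if (!all(req %in% names(counts)))
    stop("counts must have columns experiment, dose, cells_seeded, colonies")
  if (any(counts$colonies < 0) || any(counts$cells_seeded <= 0) ||
      any(counts$dose < 0))
    stop("invalid counts: need colonies >= 0, cells_seeded > 0, doses >= 0")
  if (length(unique(counts$dose)) < 3 || !any(counts$dose == 0))
    stop("need at least 3 distinct doses including dose 0")
  has0 <- tapply(counts$dose == 0, counts$experiment, any)
  if (!all(has0))
    stop("plating efficiency unidentifiable: experiments without dose-0 data: ",
         paste(names(has0)[!has0], collapse = ", "))
  if (all(counts$colonies == 0))
    stop("all colony counts are zero; no survival information")
  invisible(counts)
}

# saturated Poisson log-likelihood (mu_hat = observed count; 0*log(0) = 0)
.lq_loglik_sat <- function(k) sum(ifelse(k > 0, k * log(k) - k, 0))

#' Fit the linear-quadratic survival model by maximum likelihood
#'
#' Maximises the Poisson log-likelihood over `(alpha, beta)` (both constrained
#' non-negative) with per-experiment plating efficiencies profiled out. The
#' optimiser is started from the log-linear least-squares solution on observed
#' surviving fractions.
#'
#' @param counts data frame with columns `experiment`, `dose` (Gy),
#'   `cells_seeded`, `colonies`; at least 3 distinct doses including 0, and a
#'   dose-0 dish in every experiment.
#' @return Object of class `lq_fit`: `alpha`, `beta`, `pe` (named per
#'   experiment), `loglik`, `deviance`, `n_params`, `n_dishes`, `at_bound`
#'   flag, and the initialisation used.
#' @export
fit_lq <- function(counts) {
  .lq_validate(counts)
  # initialisation: log-linear LS on observed surviving fractions
  d0 <- counts$dose == 0
  pe0 <- tapply(counts$colonies[d0], counts$experiment[d0], sum) /
    tapply(counts$cells_seeded[d0], counts$experiment[d0], sum)
  sf <- counts$colonies / (counts$cells_seeded * pmax(pe0[counts$experiment], 1e-12))
  pos <- sf > 0 & counts$dose > 0
  init <- c(0, 0)
  if (sum(pos) >= 2) {
    y <- -log(sf[pos]); D <- counts$dose[pos]
    cf <- tryCatch(unname(stats::lm.fit(cbind(D, D^2), y)$coefficients),
                   error = function(e) c(0, 0))
    init <- pmax(ifelse(is.finite(cf), cf, 0), 0)
  }
  nll <- function(par) -.lq_profile(par, counts)$loglik
  opt <- stats::optim(init, nll, method = "L-BFGS-B",
                      lower = c(0, 0), upper = c(10, 10),
                      control = list(factr = 1e2, maxit = 500))
  prof <- .lq_profile(opt$par, counts)
  structure(list(alpha = opt$par[1], beta = opt$par[2],
                 pe = prof$pe, loglik = prof$loglik,
                 loglik_init = -nll(init),
                 deviance = 2 * (.lq_loglik_sat(counts$colonies) - prof$loglik),
                 n_params = 2 + length(prof$pe),
                 n_dishes = nrow(counts),
                 at_bound = opt$par < 1e-8,
                 init = init, convergence = opt$convergence),
            class = "lq_fit")
}

#' Predicted surviving fraction of a linear-quadratic fit
#' @param fit an `lq_fit`.
#' @param dose doses in Gy.
#' @return `exp(-(alpha*D + beta*D^2))`.
#' @export
surviving_fraction <- function(fit, dose) {
  stopifnot(inherits(fit, "lq_fit"), all(dose >= 0))
  exp(-(fit$alpha * dose + fit$beta * dose^2))
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf("Linear-quadratic fit: alpha = %.4f /Gy, beta = %.4f /Gy^2\n",
              x$alpha, x$beta))
  cat(sprintf("  plating efficiencies: %s\n",
              paste(sprintf("%s=%.3f", names(x$pe), x$pe), collapse = ", ")))
  cat(sprintf("  log-likelihood %.2f over %d dishes (%d parameters)\n",
              x$loglik, x$n_dishes, x$n_params))
  invisible(x)
}

# joint fit sharing (alpha, beta) across two tables (separate PEs per
# experiment per line); experiments are namespaced to avoid collisions
.lq_joint <- function(countsA, countsB) {
  a <- countsA; a$experiment <- paste0("A.", a$experiment)
  b <- countsB; b$experiment <- paste0("B.", b$experiment)
  both <- rbind(a, b)
  nll <- function(par) -.lq_profile(par, both)$loglik
  fa <- fit_lq(countsA); fb <- fit_lq(countsB)
  init <- pmax(c(mean(c(fa$alpha, fb$alpha)), mean(c(fa$beta, fb$beta))), 0)
  opt <- stats::optim(init, nll, method = "L-BFGS-B",
                      lower = c(0, 0), upper = c(10, 10),
                      control = list(factr = 1e2, maxit = 500))
  ll <- -opt$value
  list(fitA = fa, fitB = fb, loglik_joint = ll,
       deviance_joint = 2 * (.lq_loglik_sat(both$colonies) - ll),
       n = nrow(both))
}

#' Compare two clonogenic survival curves
#'
#' Fits (i) a joint model sharing `(alpha, beta)` across the two lines with
#' separate plating efficiencies and (ii) separate parameters per line, and
#' computes the deviance-based extra-sum-of-squares F statistic
#' `F = ((Dev_joint - Dev_sep)/2) / (Dev_sep/df_sep)` with
#' `df_sep = n_dishes - n_params_sep`, referred to `F(2, df_sep)`. An exact
#' likelihood-ratio chi-square is available as an option.
#'
#' @param countsA,countsB colony-count tables (see [fit_lq()]).
#' @param method `"F"` (default, deviance F-test) or `"lrt"`.
#' @return List: `statistic`, `df_num`, `df_den`, `p_value`, plus both fits.
#' @export
compare_curves <- function(countsA, countsB, method = c("F", "lrt")) {
  method <- match.arg(method)
  jt <- .lq_joint(countsA, countsB)
  dev_sep <- jt$fitA$deviance + jt$fitB$deviance
  n_params_sep <- jt$fitA$n_params + jt$fitB$n_params
  df_sep <- jt$n - n_params_sep
  if (df_sep <= 0)
    stop("no residual degrees of freedom to compare curves (df_sep <= 0)")
  ddev <- max(jt$deviance_joint - dev_sep, 0)
  if (method == "F") {
    Fstat <- (ddev / 2) / (dev_sep / df_sep)
    list(statistic = Fstat, df_num = 2, df_den = df_sep,
         p_value = stats::pf(Fstat, 2, df_sep, lower.tail = FALSE),
         method = "deviance F-test", fitA = jt$fitA, fitB = jt$fitB)
  } else {
    list(statistic = ddev, df_num = 2, df_den = NA_real_,
         p_value = stats::pchisq(ddev, 2, lower.tail = FALSE),
         method = "likelihood-ratio chi-square",
         fitA = jt$fitA, fitB = jt$fitB)
  }
}

#' Doubling time by semi-log regression in the exponential growth phase
#'
#' Ordinary least squares of `ln(count)` on time within the given window;
#' `T_d = ln(2) / slope`.
#'
#' @param growth data frame with columns `time` (hours) and `cell_count`.
#' @param window length-2 numeric range of times to fit (inclusive); default
#'   the full range.
#' @return Doubling time in hours.
#' @export
doubling_time <- function(growth, window = range(growth$time)) {
  stopifnot(all(c("time", "cell_count") %in% names(growth)))
  sel <- growth$time >= window[1] & growth$time <= window[2]
  g <- growth[sel, , drop = FALSE]
  if (nrow(g) < 2) stop("need at least 2 time points inside the window")
  if (any(g$cell_count <= 0)) stop("cell counts must be positive in the window")
  slope <- stats::coef(stats::lm(log(cell_count) ~ time, data = g))[["time"]]
  if (slope <= 0) stop("no exponential growth: non-positive slope in window")
  log(2) / slope
}
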