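---
title: "Models and methods behind radpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind radpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

radpipe implements the computational chain used to characterise the
radiation response of tumour cell lines from time-course transcriptomics:
clonogenic survival modelling, spline-based time-course differential
expression, early/late responder classification, gene association network
reconstruction with consensus-centrality gene ranking, pathway
over-representation, and copy-number/expression integration. Because such
studies rarely deposit raw data, the package ships a synthetic-data module
that generates every input with recorded ground truth; all statements about
recovery rates in the test suite refer to that recorded truth.

## Study design emulated by the generator

`gen_timecourse()` emulates a two-condition design — irradiated (8 Gy)
versus sham-irradiated control — sampled at 0.25, 2, 7, 12, 24, 48, 72 and
96 h after irradiation with 3 independent replicate experiments per
condition, measured on the log2 scale. Values are emitted already
normalised: array preprocessing, probe-to-gene mapping and batch correction
are upstream concerns the pipeline deliberately does not model.

Per gene the control trajectory is `intercept + B(t) b_g`, with `B` the
3-df natural cubic spline basis over the design times, intercepts uniform
on 6–12 log2 units and baseline coefficients `b_g ~ N(0, baseline_sd^2)`
(default 1). A fraction `prop_de` of genes receives a treatment difference
`g0 + B(t) g` whose offset and shape coefficients are `N(0, effect_sd^2)`;
the remaining genes have identical expected trajectories in both
conditions, which is what makes the null simulations exact. Residual noise
is `N(0, sigma_g^2)` with `sigma_g^2 ~ d0 * s0_sq / ChiSq(d0)` (defaults
`d0 = 4`, `s0_sq = 0.05`), i.e. the scaled inverse-chi-square hyperprior
that the empirical-Bayes moderation stage assumes — so moderation is tested
against a correctly specified target. Each generator draws from its own RNG
stream (`seed` plus a fixed per-generator offset), so adding one generator
never perturbs another's output.

What the generator does **not** emulate: probe-level noise, scanner
artifacts, batch structure, correlated gene-gene noise outside the network
module, and autocorrelated within-trajectory noise. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
model, not robustness to microarray artifacts.

## Time-course differential expression

The basis (`natural_spline_basis()`) places boundary knots at the extreme
design times and `df - 1` interior knots at quantiles of the *distinct*
times (quantile placement is the common default when only the degrees of
freedom are specified). Per gene, expression is regressed on
`[1, B1..BK, x, x*B1..x*BK]` where `x` indicates the treated condition; the
tested null is that the whole treatment block — offset *and* shape,
`q = df + 1 = 4` coefficients — is zero, because a level shift between
conditions is a real treatment difference. A shape-only test (`q = df`) is
available via `test = "shape"` for users who want the offset absorbed into
the null.

Variance moderation follows the standard empirical-Bayes moment approach:
with `e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2)`, the prior degrees of
freedom solve `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))` via a
Newton iteration on the trigamma inverse, and `s0^2` follows from
`mean(e)`. When the observed spread of `e` does not exceed its sampling
component the estimator returns `d0 = Inf` and all gene variances pool to
`s0^2` — a defined branch, not an error. Genes with zero residual degrees
of freedom are excluded from estimation with a warning. The moderated
statistic `F = ((RSS0 - RSS1)/q) / s_tilde^2` is referred to
`F(q, d0 + d_g)`, and `d0` forced to 0 reproduces the ordinary per-gene
F-test exactly, which the tests exploit as an oracle equivalence.

Static (clone-vs-parental) contrasts use the same variance squeeze with a
moderated t-statistic; a gene is called only when `|log2FC| > 0.5` *and*
`FDR < 0.05`, both strict, matching the convention that a fold change
printed as "higher than 0.5" excludes the boundary. Early/late responder
classification computes the per-time-point fold change from replicate
means on the log2 scale, then exponentiates; a DE gene is *early* if
`FC > 2.0` or `FC < 0.5` (strict) at any time up to and including 24 h, and
*late* if that happens in (24, 96] h. The 24 h sample counts as day 1.

## Gene association networks

Trajectories of the temporally DE genes feed the network stage. By default
the treated-condition trajectories are used (the networks summarise the
radiation response); `control` and `difference` are available because the
choice is a genuine design freedom. Replicates are averaged per time point,
giving one smooth trajectory per gene, and the unevenly spaced times are
weighted by trapezoid rule half-intervals normalised to sum 1.

The weighted correlation is shrunk towards the identity with the
Schaefer–Strimmer intensity `lambda* = sum Var-hat(r_ij) / sum r_ij^2`
(clipped to [0, 1]). For weighted observations the variance term
generalises the usual cross-product formula as
`h1^3 * sum_k w_k^2 (w_kij - wbar_ij)^2` with `h1 = 1/(1 - sum w^2)`,
which reduces exactly to `n/(n-1)^3 * sum (w_kij - wbar_ij)^2` for uniform
weights; the uniform case is what the brute-force oracle in the test suite
checks. Partial correlations come from the inverse of the shrunken matrix,
`p_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)`. A singular correlation with
`lambda* = 0` raises an error advising shrinkage rather than silently
regularising.

Edge significance uses a two-component mixture over all off-diagonal
partial correlations: a null density
`f0(p; kappa) = (1 - p^2)^((kappa-3)/2) Gamma(kappa/2) /
(sqrt(pi) Gamma((kappa-1)/2))` with effective degrees of freedom `kappa`
estimated by maximum likelihood (weighting and replicate averaging make the
nominal sample size inappropriate), and a Uniform(-1, 1) alternative. The
uniform alternative replaces the nonparametric density estimate used
elsewhere in the literature because it is deterministic and testable; the
posterior `prob = (1 - eta0) fA / f` is then monotone in `|p|` by
construction. Optimisation runs on transformed parameters
(logit eta0 bounded in [-5, 10], log(kappa - 3) in [log 0.5, log 2e5]) with
L-BFGS-B; non-convergence is an error, never a silent fallback. Edges are
kept at posterior `prob >= 0.95`, closed threshold, ties included; isolated
nodes are retained in the network object and both node counts are
reported.

The synthetic GGM behind `gen_network_timeseries()` uses a unit-diagonal
precision matrix with `-rho` on the adjacency pattern, so true edges have
partial correlation exactly `rho`. Random graphs are drawn under a per-node
degree cap `floor((1 - eps)/rho)`, making the precision strictly diagonally
dominant and hence positive definite for any draw; explicit edge lists
bypass the cap but are eigenvalue-checked, and an infeasible
magnitude/density combination errors with the smallest achieved eigenvalue.
Samples are i.i.d. draws from the implied correlation matrix rather than an
autoregressive process: i.i.d. sampling gives an exact analytic truth for
the conditional-independence structure the reconstruction must recover.

## Centrality and gene selection

Degree, shortest-path betweenness (unweighted edges) and closeness are
computed with igraph. Closeness uses the harmonic form
`sum_{u != v} 1/d(u, v)` with `1/Inf = 0`, because reconstructed networks
are routinely disconnected and classical closeness is undefined there; this
is a deliberate, documented choice. Each measure is ranked descending with
average ranks on ties (preserving the rank-sum invariant), and the
consensus is the mean of the three ranks. The top-5% cut selects
`k = round(fraction * N)` rounding half away from zero with a floor of 1 —
the only rounding convention consistent with selecting 313 of 6256, 285 of
5709 and 343 of 6859 — with boundary ties broken by consensus then
lexicographic gene id for determinism. Edges are unweighted in path
computations; partial-correlation weighting is left to the caller via
igraph if wanted.

## Enrichment, integration, validation

Gene sets are consumed as GMT. Membership is intersected with the analysis
universe *first*, then the inclusive 20–600 size window is applied, making
the filter relative to the genes the experiment detected; the universe
defaults to all detected genes rather than all annotated genes. The
over-representation p-value is the upper-tail hypergeometric
`P(X >= n_hits)` (one-sided Fisher), BH-adjusted across tested sets, with
enriched sets reported at FDR < 0.1 by default.

Copy-number integration assigns each gene the call of the segment
containing its midpoint under 0-based half-open `[start, end)` containment
(midpoint at a segment start is inside, at its end is not); genes outside
all segments are neutral with a flag, and overlapping segments are a hard
error. Concordance requires both the call and a DE flag in the matching
direction (`gain_up`: +1 call and log2FC > 0.5 flagged; `loss_down`: -1
and < -0.5); opposite-direction DE on a non-neutral call is `discordant`,
everything else `neutral`, and the four counts partition the joined genes.

Relative qPCR expression uses ddCt with multiple reference genes combined
by the arithmetic mean of their Ct values (the geometric mean of linear
expression is an equivalent alternative at fixed efficiency); `RQ =
2^(-ddCt)` is invariant to per-sample Ct shifts. Cross-platform validation
passes only for Spearman rho strictly greater than 0.5.

## Clonogenic survival

Colony counts are modelled as `colonies ~ Poisson(cells * PE_e * S(D))`
with `S(D) = exp(-(alpha D + beta D^2))`. Poisson is the natural likelihood
for a thinned counting process and is the assumed form behind the
"maximum likelihood" fits reported for such assays. For fixed
`(alpha, beta)` the per-experiment plating efficiencies have a closed-form
ML solution, so the optimiser runs over the two LQ parameters only,
L-BFGS-B-bounded at zero (no negative LQ parameters; fits ending at the
bound are flagged), started from the log-linear least-squares solution on
observed surviving fractions. The fitted log-likelihood is checked against
the starting point in the tests (monotonicity), and on noiseless expected
counts the optimum sits at the generating parameters.

Curves are compared by a deviance-based extra-sum-of-squares F-test:
`F = ((Dev_joint - Dev_sep)/2) / (Dev_sep / df_sep)` on `(2, df_sep)`
degrees of freedom, where the joint model shares `(alpha, beta)` across
lines but keeps separate plating efficiencies. The exact likelihood-ratio
chi-square is exposed via `method = "lrt"` since the original F-test's
precise form is not recoverable from the literature citation alone. The
F approximation assumes dish-level expected counts large enough for the
deviance to be roughly chi-square; at a few colonies per dish it
over-rejects mildly, so calibration checks use generously seeded dishes.
Doubling times come from ordinary least squares of `ln(count)` on time
within a user-chosen exponential window, `T_d = ln 2 / slope`, with a
non-positive slope treated as "no exponential growth".

## Problem sizes and numerical conventions

The test and acceptance suites run at desk scale, chosen so the whole
battery completes in minutes while leaving the statistical checks
well-powered: 1000–2000 genes for DE power/calibration (20 null seeds
pooled), a 100-node/40-edge GGM with 200 samples for network recovery, 5000
draws for mixture recovery and null pass-rate checks, 500 replicates for
the F-test level, and graphs of up to 30 nodes wherever a brute-force
all-pairs oracle is the reference. Key numerical conventions: the trigamma
inverse iterates Newton to relative tolerance 1e-10; `lambda*` is clipped
to [0, 1] and a zero off-diagonal sum maps to full shrinkage; partial
correlations of zero-variance trajectories are set to 0 with a warning;
BH adjustment validates inputs and delegates to the standard step-up
implementation; all interval data are 0-based half-open.

## Known limitations

Network reconstruction from eight weighted time points is conservative:
with so few effective observations the shrinkage intensity is large and few
edges clear the 0.95 posterior, which mirrors the method's behaviour on
short time courses generally. The mixture's uniform alternative
underestimates the posterior when true partial correlations cluster tightly
just outside the null bulk. The LQ deviance F-test is approximate at low
dish counts (see above). None of the modules models between-array
normalisation error, and the early/late classification inherits the
replicate-mean convention — single-replicate outliers can flip a
fold-change crossing.
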