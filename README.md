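# radpipe

Analysis pipeline for radiation-response time-course transcriptomics in
tumour cell lines — the computational chain used to ask how a cell line and
its radioresistant/radiosensitive subclones differ in their response to
ionizing radiation:

- **Clonogenic survival**: maximum-likelihood fits of the linear-quadratic
  model S(D) = exp(−(αD + βD²)) to colony counts
  (`colonies ~ Poisson(cells · PE · S(D))`, plating efficiencies profiled
  per experiment), deviance F-tests between curves, and semi-log doubling
  times T_d = ln2/slope.
- **Time-course differential expression**: per-gene regression of log2
  expression on a 3-df natural cubic spline with a treatment block
  (irradiated vs sham), empirical-Bayes moderated F-tests
  (s̃² = (d₀s₀² + d_g s_g²)/(d₀ + d_g)), Benjamini–Hochberg FDR, plus
  static clone-vs-parental contrasts (|log2FC| > 0.5, FDR < 0.05) and
  early/late responder classification (fold change > 2.0 or < 0.5 within
  day 1, or days 2–4).
- **Gene association networks**: trapezoid-weighted dynamical correlation of
  DE-gene trajectories, Schäfer–Strimmer shrinkage to the identity,
  partial correlations p_ij = −Ω_ij/√(Ω_iiΩ_jj), and per-edge posterior
  probabilities from a two-component mixture (null partial-correlation
  density with fitted effective df κ vs a uniform alternative); edges kept
  at posterior ≥ 0.95.
- **Consensus centrality**: degree, shortest-path betweenness and harmonic
  closeness, each rank-transformed; the consensus is the mean rank and the
  top 5% (round half away from zero) are the candidate key genes.
- **Pathway enrichment**: one-sided Fisher tests over GMT gene sets
  filtered to 20–600 genes within the detected universe, BH-adjusted.
- **Integration**: copy-number calls mapped to genes by midpoint
  containment and crossed with static DE (gain∧up / loss∧down), and qPCR
  ΔΔCt relative quantification validated against array fold changes by
  Spearman's rho > 0.5.
- **Synthetic data with ground truth** for every input (spline
  trajectories with a scaled inverse-chi-square variance hyperprior, sparse
  Gaussian graphical models with exact edge partial correlations, spiked
  gene sets, segmented CNA profiles, Poisson colony counts), so every stage
  is testable end-to-end without external data.

Intended users: bioinformaticians analysing irradiated-vs-control
time-course experiments, and methodologists who want a tested, transparent
reference implementation of this analysis chain.

## Worked example

The `analysis/` directory is a numbered workflow over synthetic data for a
parental line and two subclones ("SP" radiosensitive, "RP" radioresistant);
each script prints what it found and writes tables under `results/`.

```sh
Rscript analysis/01_simulate.R       # inputs + recorded truth
Rscript analysis/02_clonogenic.R
Rscript analysis/03_timecourse_de.R
Rscript analysis/04_network.R
Rscript analysis/05_enrichment.R
Rscript analysis/06_integration.R
```

Stage 2 fits and compares the survival curves (truth: α = 0.30/0.45/0.18
per Gy for parental/SP/RP, β = 0.03 Gy⁻²):

```
LQ fits (alpha /Gy, beta /Gy^2, SF2):
     line alpha   beta   sf2 loglik
 parental 0.284 0.0315 0.500  21365
       SP 0.464 0.0302 0.350  16228
       RP 0.202 0.0249 0.604  28203

Curve comparisons (deviance F-test):
   line_a line_b     F df_num df_den        p
 parental     SP  63.9      2     98 1.73e-18
 parental     RP  45.1      2     98 1.28e-14
       SP     RP 201.1      2     98 2.05e-35

Doubling times (h): parental=24.3 SP=29.5 RP=28.5
```

SF2 is the surviving fraction at 2 Gy — lower for the sensitive subclone,
higher for the resistant one — and all three curves differ with p ≪ 0.0001.
Stage 3 recovers the planted temporally DE genes:

```
parental  124 temporally DE genes (FDR<0.05); sensitivity 0.98, empirical FDR 0.048; 72 early, 77 late
SP        118 temporally DE genes (FDR<0.05); sensitivity 0.95, empirical FDR 0.034; 72 early, 81 late
RP        120 temporally DE genes (FDR<0.05); sensitivity 0.93, empirical FDR 0.067; 70 early, 78 late
```

and stage 4 reconstructs the gene association network over those genes,
ranks nodes by consensus centrality and extracts a hub's first
neighborhood:

```
parental  lambda*=0.48; 124 nodes (9 connected), 7 edges; top 5% = 6 genes; hub g0581 has 4 first-neighborhood genes
```

(Short 8-point trajectories shrink hard and yield sparse networks — the
expected behaviour at this sample size.) Stages 5 and 6 report the spiked
pathway recovery, the gain∧up / loss∧down concordance counts and the ΔΔCt
validation (`Spearman rho = 1.00 -> PASS`).

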