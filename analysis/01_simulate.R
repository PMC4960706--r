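#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with recorded ground truth.
# Emulated design: an irradiated (8 Gy) vs sham-irradiated time course
# (0.25-96 h, 3 replicate experiments) for a parental tumour line and two
# derived subclones of altered radiosensitivity ("SP" radiosensitive,
# "RP" radioresistant), plus clonogenic colony counts, growth curves,
# segmented copy-number profiles and qPCR-style Ct tables.

suppressPackageStartupMessages(library(radpipe))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

lines <- list(parental = 1L, SP = 2L, RP = 3L)
for (nm in names(lines)) {
  sim <- gen_timecourse(sim_config(n_genes = 600, prop_de = 0.2,
                                   effect_sd = 1, d0 = 4, s0_sq = 0.05,
                                   seed = lines[[nm]]))
  write_expression_tsv(sim$expr, sprintf("results/data/%s_expression.tsv", nm))
  write_table_tsv(sim$design, sprintf("results/data/%s_design.tsv", nm))
  write_table_tsv(data.frame(gene = sim$truth$de_genes),
                  sprintf("results/data/%s_true_de_genes.tsv", nm))
  cat(sprintf("%-9s %d genes x %d samples, %d planted DE genes\n",
              nm, nrow(sim$expr), ncol(sim$expr),
              length(sim$truth$de_genes)))
}

# clonogenic survival: subclones differ in the linear component
lq <- data.frame(line = c("parental", "SP", "RP"),
                 alpha = c(0.30, 0.45, 0.18), beta = c(0.030, 0.030, 0.030),
                 pe = c(0.50, 0.45, 0.55))
write_table_tsv(lq, "results/data/lq_truth.tsv")
for (i in seq_len(nrow(lq))) {
  counts <- gen_colony_counts(lq$alpha[i], lq$beta[i], lq$pe[i],
                              cells_seeded = c(200, 400, 800),
                              n_experiments = 3, seed = 10 + i)
  write_table_tsv(counts, sprintf("results/data/%s_colonies.tsv", lq$line[i]))
}

# growth curves around the reported doubling times (24/29/30 h)
set.seed(99)
td <- c(parental = 24, SP = 29, RP = 30)
for (nm in names(td)) {
  t <- seq(0, 72, 12)
  growth <- data.frame(time = t,
                       cell_count = round(2e4 * 2^(t / td[[nm]]) *
                                            exp(rnorm(length(t), sd = 0.03))))
  write_table_tsv(growth, sprintf("results/data/%s_growth.tsv", nm))
}
cat("wrote clonogenic and growth tables for", nrow(lq), "lines\n")
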