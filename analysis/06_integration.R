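#!/usr/bin/env Rscript
# Stage 6: integration of copy-number calls with clone-vs-parental static
# differential expression (gain&up / loss&down concordance), and the qPCR
# delta-delta-Ct technical validation against array fold changes.
#
# The status-quo clone matrices are built from the parental control samples
# plus planted log2 shifts on a gene subset, so the static contrast has a
# known truth; CNA segments are simulated independently and the concordant
# subset (gain&up / loss&down) is what the integration reports.

suppressPackageStartupMessages(library(radpipe))
dir.create("results/integration", showWarnings = FALSE, recursive = TRUE)

par_expr <- read_expression_tsv("results/data/parental_expression.tsv")
par_design <- read_table_tsv("results/data/parental_design.tsv")
ctrl <- par_design$sample[par_design$condition == "control"]
base <- par_expr[, ctrl]

for (nm in c("SP", "RP")) {
  seed <- 70 + nchar(nm) + (nm == "RP")
  set.seed(seed)
  shifted <- sample(rownames(base), 60)
  lfc_true <- stats::setNames(sample(c(-1, 1), 60, TRUE) * runif(60, 0.8, 4),
                              shifted)
  clone <- base + matrix(rnorm(length(base), sd = 0.1), nrow(base))
  clone[shifted, ] <- clone[shifted, ] + lfc_true
  colnames(clone) <- sub("con", nm, ctrl)

  sde <- static_de(base, clone, lfc_threshold = 0.5, fdr_threshold = 0.05)
  write_table_tsv(sde, sprintf("results/integration/%s_static_de.tsv", nm))

  annot <- data.frame(gene = sde$gene,
                      chrom = paste0("chr", 1 + seq_along(sde$gene) %% 3),
                      midpoint = 5000 * seq_along(sde$gene))
  cna <- gen_cna_profile(annot, n_segments = 6, seed = seed)
  write_table_tsv(cna$segments,
                  sprintf("results/integration/%s_segments.tsv", nm))
  calls <- map_genes_to_calls(annot, cna$segments)
  conc <- concordant_genes(sde, calls, lfc_threshold = 0.5)
  write_table_tsv(conc, sprintf("results/integration/%s_concordance.tsv", nm))
  cnt <- attr(conc, "counts")
  cat(sprintf(paste0("%-3s static DE: %d/%d planted shifts recovered ",
                     "(%d flagged); concordance: %d gain&up, %d loss&down, ",
                     "%d discordant\n"),
              nm, sum(sde$de & sde$gene %in% shifted), length(shifted),
              sum(sde$de), cnt["gain_up"], cnt["loss_down"],
              cnt["discordant"]))
}

# qPCR technical validation: Ct tables consistent with the array fold changes
set.seed(123)
targets <- sprintf("TGT%d", 1:8)
true_lfc <- rnorm(8, sd = 1.5)
ct <- do.call(rbind, lapply(c("cal", "trt"), function(s) {
  shift <- if (s == "trt") true_lfc else rep(0, 8)
  data.frame(sample = s,
             assay = c(targets, "ACTB", "GAPDH"),
             ct = c(25 - shift + rnorm(8, sd = 0.15), 20, 22))
}))
write_table_tsv(ct, "results/integration/qpcr_ct.tsv")
rq <- sapply(targets, function(tg) {
  r <- ddct_relative_expression(ct[ct$assay %in% c(tg, "ACTB", "GAPDH"), ],
                                tg, c("ACTB", "GAPDH"), "cal")
  r$rq[r$sample == "trt"]
})
val <- validate_platforms(log2(rq), true_lfc)
write_table_tsv(data.frame(target = targets, qpcr_log2fc = log2(rq),
                           array_log2fc = true_lfc),
                "results/integration/qpcr_validation.tsv")
cat(sprintf("qPCR validation: Spearman rho = %.2f -> %s\n",
            val$rho, ifelse(val$pass, "PASS", "FAIL")))
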