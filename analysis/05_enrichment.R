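#!/usr/bin/env Rscript
# Stage 5: pathway over-representation of the top-5% network genes in a
# synthetic gene-set collection spiked with sets built around those genes
# (so detection can be checked against the recorded truth). Sets outside the
# 20-600 size window are removed before testing, as in the study design.

suppressPackageStartupMessages(library(radpipe))
dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)

for (nm in c("parental", "SP", "RP")) {
  de <- read_table_tsv(sprintf("results/de/%s_de.tsv", nm))
  universe <- de$gene  # all detected genes of the experiment
  top <- read_table_tsv(sprintf("results/network/%s_top_genes.tsv", nm))$gene
  de_genes <- de$gene[de$fdr < 0.05]

  gs <- gen_gene_sets(universe, n_sets = 40, size_range = c(20, 120),
                      enriched_in = de_genes, n_enriched = 4,
                      enrich_frac = 0.7, seed = 50 + nchar(nm))
  write_gmt(gs$collection, sprintf("results/enrichment/%s_sets.gmt", nm))

  coll <- filter_sets(read_gmt(sprintf("results/enrichment/%s_sets.gmt", nm)),
                      universe, min_size = 20, max_size = 600)
  enr <- fisher_enrichment(de_genes, universe, coll)
  write_table_tsv(enr, sprintf("results/enrichment/%s_enrichment.tsv", nm))

  sig <- enr$set[enr$fdr < 0.1]
  hit <- intersect(sig, gs$truth$enriched_sets)
  cat(sprintf("%-9s %d/%d sets enriched at FDR<0.1; %d/%d spiked sets found\n",
              nm, length(sig), nrow(enr), length(hit),
              length(gs$truth$enriched_sets)))
}
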