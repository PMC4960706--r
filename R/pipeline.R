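#' Default pipeline configuration
#'
#' All thresholds default to the study's quoted values: time-course DE at
#' FDR < 0.05, static DE at |log2FC| > 0.5 and FDR < 0.05, early/late
#' fold-change windows 2.0/0.5, edge posterior 0.95, top 5% consensus
#' centrality, gene-set size filter 20-600, enrichment reporting at FDR < 0.1.
#' Every value can be overridden, and each stage can be toggled.
#'
#' @param outdir output directory for stage files.
#' @param seed integer seed for the synthetic inputs.
#' @param ... overrides for any config entry (see defaults in the source).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("radpipe_run_"), seed = 1L, ...) {
  cfg <- list(
    outdir = outdir, seed = as.integer(seed),
    n_genes = 300, prop_de = 0.2, effect_sd = 1, d0 = 4, s0_sq = 0.05,
    de_fdr = 0.05, static_lfc = 0.5, static_fdr = 0.05,
    fc_hi = 2.0, fc_lo = 0.5,
    gan_condition = "treated", edge_prob = 0.95,
    top_fraction = 0.05,
    set_min = 20, set_max = 600, enrich_fdr = 0.1,
    n_sets = 40, n_enriched = 4,
    n_segments = 6, n_chromosomes = 2,
    stages = c(simulate = TRUE, de = TRUE, earlylate = TRUE, gan = TRUE,
               centrality = TRUE, enrichment = TRUE, integration = TRUE)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$de_fdr > 0, cfg$de_fdr < 1, cfg$edge_prob > 0,
            cfg$edge_prob <= 1, cfg$top_fraction > 0, cfg$top_fraction <= 1,
            cfg$set_min >= 1, cfg$set_max >= cfg$set_min)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with config entries (see [pipeline_config()]).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$stages)) vals$stages <- unlist(vals$stages)
  do.call(pipeline_config, vals)
}

#' Validate pipeline inputs
#'
#' Checks the expression/design pair for schema and consistency (every matrix
#' column present in the design and vice versa, both conditions covering the
#' identical time points) and, when given, GMT well-formedness.
#'
#' @param expr genes x samples matrix (or `NULL`).
#' @param design design data frame (or `NULL`).
#' @param gmt_path optional GMT file path.
#' @return Character vector of blocking issues (empty when clean).
#' @export
validate_inputs <- function(expr = NULL, design = NULL, gmt_path = NULL) {
  issues <- character(0)
  if (!is.null(expr) && !is.null(design)) {
    req <- c("sample", "condition", "time_h", "replicate")
    if (!all(req %in% names(design))) {
      issues <- c(issues, "design lacks required columns")
    } else {
      miss <- setdiff(colnames(expr), design$sample)
      if (length(miss))
        issues <- c(issues, paste("samples missing from design:",
                                  paste(miss, collapse = ", ")))
      extra <- setdiff(design$sample, colnames(expr))
      if (length(extra))
        issues <- c(issues, paste("design samples missing from matrix:",
                                  paste(extra, collapse = ", ")))
      if (anyNA(expr)) issues <- c(issues, "expression matrix has missing values")
      tc <- sort(unique(design$time_h[design$condition == "control"]))
      tt <- sort(unique(design$time_h[design$condition == "treated"]))
      if (!identical(tc, tt)) {
        lack <- union(setdiff(tc, tt), setdiff(tt, tc))
        issues <- c(issues, paste("conditions do not share time points:",
                                  paste(lack, collapse = ", ")))
      }
    }
  }
  if (!is.null(gmt_path)) {
    ok <- tryCatch({ read_gmt(gmt_path); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) issues <- c(issues, paste("GMT:", ok))
  }
  issues
}

.stage_files <- function(outdir) {
  file.path(outdir, c(expr = "expression.tsv", design = "design.tsv",
                      de = "de.tsv", earlylate = "early_late.tsv",
                      edges = "edges.tsv", centrality = "centrality.tsv",
                      top = "top_genes.tsv", gmt = "sets.gmt",
                      enrich = "enrichment.tsv", segments = "segments.tsv",
                      annot = "gene_annotation.tsv",
                      concordance = "concordance.tsv"))
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate, time-course DE,
#' early/late classification, gene association network, consensus centrality,
#' pathway enrichment, copy-number integration — writing each stage's table
#' under `config$outdir` and returning a manifest with per-file MD5 checksums
#' so deterministic re-runs can be verified.
#'
#' @param config a [pipeline_config()].
#' @return The run manifest (list): config echo, file checksums, timestamps,
#'   collected warnings.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- .stage_files(config$outdir)
  names(files) <- c("expr", "design", "de", "earlylate", "edges", "centrality",
                    "top", "gmt", "enrich", "segments", "annot", "concordance")
  st <- config$stages
  warnings_log <- character(0)
  note <- function(w) { warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning") }
  t0 <- Sys.time()

  sim <- NULL; de <- NULL
  withCallingHandlers({
    if (isTRUE(st[["simulate"]])) {
      cfg <- sim_config(n_genes = config$n_genes, prop_de = config$prop_de,
                        effect_sd = config$effect_sd, d0 = config$d0,
                        s0_sq = config$s0_sq, seed = config$seed)
      sim <- gen_timecourse(cfg)
      write_expression_tsv(sim$expr, files["expr"])
      write_table_tsv(sim$design, files["design"])
    }
    if (isTRUE(st[["de"]])) {
      expr <- read_expression_tsv(files["expr"])
      design <- read_table_tsv(files["design"])
      de <- timecourse_de(expr, design, fdr_threshold = config$de_fdr)
      write_table_tsv(de$table, files["de"])
    }
    if (isTRUE(st[["earlylate"]])) {
      expr <- read_expression_tsv(files["expr"])
      design <- read_table_tsv(files["design"])
      de_tab <- read_table_tsv(files["de"])
      de_genes <- de_tab$gene[de_tab$fdr < config$de_fdr]
      el <- classify_early_late(expr, design, de_genes,
                                fc_hi = config$fc_hi, fc_lo = config$fc_lo)
      write_table_tsv(el$class, files["earlylate"])
    }
    if (isTRUE(st[["gan"]])) {
      expr <- read_expression_tsv(files["expr"])
      design <- read_table_tsv(files["design"])
      de_tab <- read_table_tsv(files["de"])
      de_genes <- de_tab$gene[de_tab$fdr < config$de_fdr]
      if (length(de_genes) < 5)
        stop("gan stage: fewer than 5 temporally DE genes")
      gan <- build_gan(expr, design, de_genes,
                       condition = config$gan_condition,
                       threshold = config$edge_prob)
      write_table_tsv(gan$network$edges, files["edges"])
    }
    if (isTRUE(st[["centrality"]])) {
      edges <- read_table_tsv(files["edges"])
      de_tab <- read_table_tsv(files["de"])
      nodes <- de_tab$gene[de_tab$fdr < config$de_fdr]
      net <- structure(list(nodes = nodes, edges = edges,
                            threshold = config$edge_prob, model = NULL),
                       class = "gene_network")
      cent <- compute_centralities(net)
      write_table_tsv(cent, files["centrality"])
      top <- top_fraction(cent, config$top_fraction)
      write_table_tsv(data.frame(gene = top), files["top"])
    }
    if (isTRUE(st[["enrichment"]])) {
      de_tab <- read_table_tsv(files["de"])
      universe <- de_tab$gene
      top <- read_table_tsv(files["top"])$gene
      gs <- gen_gene_sets(universe, n_sets = config$n_sets,
                          size_range = c(max(2, config$set_min),
                                         min(length(universe), 120)),
                          enriched_in = top, n_enriched = config$n_enriched,
                          seed = config$seed)
      write_gmt(gs$collection, files["gmt"])
      coll <- filter_sets(read_gmt(files["gmt"]), universe,
                          min_size = config$set_min, max_size = config$set_max)
      enr <- fisher_enrichment(top, universe, coll)
      write_table_tsv(enr, files["enrich"])
    }
    if (isTRUE(st[["integration"]])) {
      de_tab <- read_table_tsv(files["de"])
      genes <- de_tab$gene
      annot <- data.frame(gene = genes,
                          chrom = paste0("chr", 1 + (seq_along(genes) %%
                                                       config$n_chromosomes)),
                          midpoint = 1000 * seq_along(genes),
                          stringsAsFactors = FALSE)
      write_table_tsv(annot, files["annot"])
      cna <- gen_cna_profile(annot, n_segments = config$n_segments,
                             seed = config$seed)
      write_table_tsv(cna$segments, files["segments"])
      calls <- map_genes_to_calls(annot, cna$segments)
      # static contrast: treated vs control late samples of the simulation
      expr <- read_expression_tsv(files["expr"])
      design <- read_table_tsv(files["design"])
      late <- design$time_h >= 48
      sde <- static_de(expr[, design$sample[late & design$condition == "control"]],
                       expr[, design$sample[late & design$condition == "treated"]],
                       lfc_threshold = config$static_lfc,
                       fdr_threshold = config$static_fdr)
      conc <- concordant_genes(sde, calls, lfc_threshold = config$static_lfc)
      write_table_tsv(conc, files["concordance"])
    }
  }, warning = note)

  produced <- files[file.exists(files)]
  manifest <- list(
    config = unclass(config),
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    checksums = as.list(tools::md5sum(produced)),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest[c("config", "checksums", "warnings")],
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
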