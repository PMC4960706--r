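#' Map genes to copy-number calls via segment containment
#'
#' A gene receives the call of the segment containing its midpoint, using
#' 0-based half-open `[start, end)` containment (a midpoint equal to a segment
#' start is contained; equal to its end is not). Genes in no segment get call
#' 0 with `in_segment = FALSE`.
#'
#' @param genes data frame with columns `gene`, `chrom`, `midpoint`.
#' @param segments data frame with columns `chrom`, `start`, `end`, `call`
#'   (-1 loss, 0 neutral, +1 gain); segments must not overlap within a
#'   chromosome.
#' @return Data frame: `gene`, `chrom`, `midpoint`, `call`, `in_segment`.
#' @export
map_genes_to_calls <- function(genes, segments) {
  stopifnot(all(c("gene", "chrom", "midpoint") %in% names(genes)),
            all(c("chrom", "start", "end", "call") %in% names(segments)))
  if (any(segments$start >= segments$end))
    stop("malformed segments: start must be < end")
  call <- integer(nrow(genes))
  inseg <- logical(nrow(genes))
  for (chr in unique(genes$chrom)) {
    seg <- segments[segments$chrom == chr, , drop = FALSE]
    gi <- which(genes$chrom == chr)
    if (nrow(seg) == 0) next
    seg <- seg[order(seg$start), , drop = FALSE]
    if (any(seg$start[-1] < seg$end[-nrow(seg)]))
      stop("malformed segments: overlap on chromosome ", chr)
    idx <- findInterval(genes$midpoint[gi], seg$start)
    ok <- idx >= 1 & idx <= nrow(seg)
    ok[ok] <- genes$midpoint[gi][ok] < seg$end[idx[ok]]
    call[gi[ok]] <- seg$call[idx[ok]]
    inseg[gi[ok]] <- TRUE
  }
  data.frame(gene = genes$gene, chrom = genes$chrom,
             midpoint = genes$midpoint, call = call, in_segment = inseg,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Concordance of copy-number calls with differential expression
#'
#' Classifies each gene as `gain_up` (gain with a DE-flagged log2 fold change
#' above the threshold), `loss_down` (loss with a DE-flagged log2 fold change
#' below the negative threshold), `discordant` (DE in the direction opposite
#' its non-neutral call), or `neutral` otherwise.
#'
#' @param de_table a [static_de()] result (columns `gene`, `logFC`, `de`).
#' @param calls a [map_genes_to_calls()] result (columns `gene`, `call`).
#' @param lfc_threshold log2 fold-change magnitude used in the DE flag,
#'   default 0.5.
#' @return Data frame `gene`, `logFC`, `FC`, `call`, `status`; status counts
#'   in attribute `counts`.
#' @export
concordant_genes <- function(de_table, calls, lfc_threshold = 0.5) {
  common <- intersect(de_table$gene, calls$gene)
  dropped <- length(union(de_table$gene, calls$gene)) - length(common)
  if (dropped > 0)
    warning("inner join dropped ", dropped, " genes absent from one input")
  de <- de_table[match(common, de_table$gene), , drop = FALSE]
  cl <- calls[match(common, calls$gene), , drop = FALSE]
  up <- de$de & de$logFC > lfc_threshold
  down <- de$de & de$logFC < -lfc_threshold
  status <- rep("neutral", length(common))
  status[cl$call == 1 & up] <- "gain_up"
  status[cl$call == -1 & down] <- "loss_down"
  status[cl$call == 1 & down] <- "discordant"
  status[cl$call == -1 & up] <- "discordant"
  out <- data.frame(gene = common, logFC = de$logFC, FC = 2^de$logFC,
                    call = cl$call, status = status,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "counts") <- c(gain_up = sum(status == "gain_up"),
                           loss_down = sum(status == "loss_down"),
                           discordant = sum(status == "discordant"),
                           neutral = sum(status == "neutral"))
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' `dCt = Ct_target - mean(Ct_reference)` per sample (multiple reference genes
#' combined by the arithmetic mean of their Ct values),
#' `ddCt = dCt_sample - dCt_calibrator`, `RQ = 2^(-ddCt)`. Samples with a
#' missing target or reference Ct are skipped with a warning.
#'
#' @param ct data frame with columns `sample`, `assay`, `ct` (one Ct per
#'   sample/assay pair; Ct > 0).
#' @param target target assay name.
#' @param reference character vector of reference assay names.
#' @param calibrator calibrator sample id.
#' @return Data frame: `sample`, `delta_ct`, `delta_delta_ct`, `rq`.
#' @export
ddct_relative_expression <- function(ct, target, reference, calibrator) {
  stopifnot(all(c("sample", "assay", "ct") %in% names(ct)))
  if (any(ct$ct <= 0, na.rm = TRUE)) stop("Ct values must be positive")
  samples <- unique(ct$sample)
  if (!calibrator %in% samples) stop("calibrator sample not present")
  one <- function(s, a) {
    v <- ct$ct[ct$sample == s & ct$assay == a]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  dct <- vapply(samples, function(s) {
    tg <- one(s, target)
    rf <- vapply(reference, function(a) one(s, a), 0)
    tg - mean(rf)
  }, 0)
  ok <- is.finite(dct)
  if (!ok[match(calibrator, samples)])
    stop("calibrator is missing target or reference Ct values")
  if (any(!ok))
    warning(sum(!ok), " samples skipped for missing Ct values: ",
            paste(samples[!ok], collapse = ", "))
  samples <- samples[ok]; dct <- dct[ok]
  ddct <- dct - dct[[match(calibrator, samples)]]
  data.frame(sample = samples, delta_ct = unname(dct),
             delta_delta_ct = unname(ddct), rq = unname(2^(-ddct)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-platform validation by Spearman correlation
#'
#' Validation of qPCR fold changes against array fold changes passes iff
#' Spearman's rho strictly exceeds 0.5.
#'
#' @param rq_foldchanges qPCR-derived fold changes.
#' @param array_foldchanges matched array-derived fold changes.
#' @return List: `rho`, `pass`, `message`.
#' @export
validate_platforms <- function(rq_foldchanges, array_foldchanges) {
  stopifnot(length(rq_foldchanges) == length(array_foldchanges))
  if (length(rq_foldchanges) < 3) stop("need at least 3 paired values")
  if (stats::sd(rq_foldchanges) == 0 || stats::sd(array_foldchanges) == 0)
    return(list(rho = NA_real_, pass = FALSE,
                message = "rho undefined: constant input vector"))
  rho <- stats::cor(rq_foldchanges, array_foldchanges, method = "spearman")
  list(rho = rho, pass = rho > 0.5,
       message = if (rho > 0.5) "validation successful (rho > 0.5)"
       else "validation failed (rho <= 0.5)")
}
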