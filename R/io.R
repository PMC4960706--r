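#' Read / write the pipeline's tab-separated formats
#'
#' Expression matrices are stored with the gene id in the first column and one
#' column per sample; designs, segment tables, colony counts and generic
#' result tables are plain TSV with a header row.
#'
#' @param path file path.
#' @name radpipe-io
NULL

#' @rdname radpipe-io
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname radpipe-io
#' @param expr genes x samples matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname radpipe-io
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname radpipe-io
#' @param x data frame to write.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
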