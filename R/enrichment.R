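#' Gene set collection
#'
#' @param sets named list of character vectors (unique names, non-empty
#'   members).
#' @param description optional named character vector of set descriptions.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  stopifnot(is.list(sets), length(sets) > 0)
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  if (any(lengths(sets) == 0)) stop("member lists must be non-empty")
  if (is.null(description))
    description <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = lapply(sets, as.character),
                 description = description[names(sets)]),
            class = "gene_set_collection")
}

#' Read a GMT file
#'
#' One set per line: name TAB description TAB gene ... Missing description
#' fields are tolerated.
#'
#' @param path GMT file path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT: lines with fewer than 3 fields: ",
                     paste(utils::head(which(bad), 5), collapse = ", "))
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  desc <- stats::setNames(vapply(parts, `[`, "", 2), names(sets))
  gene_set_collection(sets, desc)
}

#' Write a gene set collection to GMT
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
}

#' Filter gene sets by size within the analysis universe
#'
#' Set membership is intersected with the universe FIRST, then the inclusive
#' size filter `min_size <= |intersection| <= max_size` is applied, so the
#' filter is relative to the genes the experiment actually detected.
#'
#' @param collection a [gene_set_collection()].
#' @param universe character vector of detected genes.
#' @param min_size,max_size inclusive size bounds, defaults 20 and 600.
#' @return Filtered [gene_set_collection()] (members intersected with the
#'   universe).
#' @export
filter_sets <- function(collection, universe, min_size = 20, max_size = 600) {
  stopifnot(inherits(collection, "gene_set_collection"), length(universe) > 0)
  inter <- lapply(collection$sets, intersect, y = universe)
  keep <- lengths(inter) >= min_size & lengths(inter) <= max_size
  if (!any(keep)) stop("no gene set passes the size filter")
  gene_set_collection(inter[keep], collection$description[keep])
}

#' One-sided Fisher over-representation test across a gene-set collection
#'
#' For each set, the 2x2 table of set membership versus query membership
#' within the universe is tested with the upper-tail hypergeometric
#' probability `P(X >= n_hits)` (equivalent to the one-sided Fisher exact
#' test), followed by Benjamini-Hochberg adjustment across the tested sets.
#'
#' @param query character vector of genes of interest; entries outside the
#'   universe are dropped with a warning.
#' @param universe character vector of all detected genes.
#' @param collection a [gene_set_collection()] (apply [filter_sets()] first
#'   for the size-filtered analysis).
#' @return Data frame ordered by p: `set`, `n_set`, `n_hits`, `p`, `fdr`,
#'   `hits` (comma-separated gene ids).
#' @export
fisher_enrichment <- function(query, universe, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(universe)
  query <- unique(query)
  out <- setdiff(query, universe)
  if (length(out)) {
    warning(length(out), " query genes outside the universe dropped")
    query <- intersect(query, universe)
  }
  U <- length(universe); Q <- length(query)
  res <- lapply(names(collection$sets), function(nm) {
    s <- intersect(collection$sets[[nm]], universe)
    hits <- intersect(s, query)
    h <- length(hits)
    p <- if (Q == 0) 1 else
      stats::phyper(h - 1, length(s), U - length(s), Q, lower.tail = FALSE)
    data.frame(set = nm, n_set = length(s), n_hits = h, p = p,
               hits = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$fdr <- benjamini_hochberg(tab$p)
  tab <- tab[order(tab$p, tab$set), c("set", "n_set", "n_hits", "p", "fdr", "hits")]
  rownames(tab) <- NULL
  tab
}
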