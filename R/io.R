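#' Read a gene-by-sample matrix from TSV/CSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#'
#' @param path File path.
#' @param sep Field separator, tab by default.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_gene_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stopf("read_gene_matrix: no such file: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Write a gene-by-sample matrix as TSV/CSV
#'
#' Values are written with 17 significant digits so a read/write round
#' trip is lossless at double precision.
#'
#' @param x Numeric matrix with rownames and colnames.
#' @param path File path.
#' @param sep Field separator.
#' @export
write_gene_matrix <- function(x, path, sep = "\t") {
  x <- as_values(x)
  fmt <- matrix(sprintf("%.17g", x), nrow = nrow(x), dimnames = dimnames(x))
  df <- data.frame(gene = rownames(x), fmt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a binary mask as TSV
#' @param mask An [sc_mask()] or binary matrix (genes x nodes).
#' @param path File path.
#' @export
write_mask <- function(mask, path) {
  m <- matrix(as.integer(mask), nrow = nrow(mask), dimnames = dimnames(mask))
  df <- data.frame(gene = rownames(m) %||% paste0("g", seq_len(nrow(m))), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary mask from TSV
#' @param path File path.
#' @return An [sc_mask()].
#' @export
read_mask <- function(path) {
  m <- read_gene_matrix(path)
  sc_mask(m)
}

#' Read a prior gene-interaction network from an edge list
#'
#' The file must have a header and two gene columns, optionally followed
#' by a numeric confidence score column. Edges with score below
#' `score_cutoff` are dropped (the conventional high-confidence cutoff
#' for curated interaction databases is 0.7).
#'
#' @param path Two- or three-column TSV edge list with header.
#' @param genes Optional character vector fixing the gene universe and
#'   order; defaults to the sorted union of genes in the file.
#' @param score_cutoff Minimum score an edge must reach; ignored when the
#'   file has no score column.
#' @return Symmetric binary adjacency matrix with zero diagonal, class
#'   `interaction_matrix`.
#' @export
read_interactions <- function(path, genes = NULL, score_cutoff = 0.7) {
  if (!file.exists(path)) stopf("read_interactions: no such file: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stopf("read_interactions: need at least two columns")
  a <- as.character(df[[1L]]); b <- as.character(df[[2L]])
  if (ncol(df) >= 3L && is.numeric(df[[3L]])) {
    keep <- df[[3L]] >= score_cutoff
    a <- a[keep]; b <- b[keep]
  }
  genes <- genes %||% sort(unique(c(a, b)))
  adj <- matrix(0L, length(genes), length(genes), dimnames = list(genes, genes))
  keep <- a %in% genes & b %in% genes & a != b
  a <- a[keep]; b <- b[keep]
  adj[cbind(a, b)] <- 1L
  adj[cbind(b, a)] <- 1L
  structure(adj, class = c("interaction_matrix", "matrix", "array"))
}
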