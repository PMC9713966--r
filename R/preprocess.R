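#' Rank-based per-sample normalization
#'
#' Normalizes one sample's gene values to `(0, 1]` by replacing each value
#' with its ascending rank divided by the number of genes. Applied per
#' sample this removes scale differences between samples (a cheap batch
#' correction) while preserving the within-sample ordering. Ties receive
#' average ranks so the output does not depend on input ordering.
#'
#' @param x A numeric vector (one sample's gene values) or a gene-by-sample
#'   matrix, in which case each column is normalized independently.
#' @return An object of the same shape as `x` with values in `(0, 1]`.
#' @examples
#' rank_normalize(c(0.2, 3.1, 1.5, 7.0))  # 0.25 0.75 0.50 1.00
#' @export
rank_normalize <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) == 0L || nrow(x) == 0L) stopf("rank_normalize: empty matrix")
    if (!all(is.finite(x))) stopf("rank_normalize: non-finite values present")
    out <- apply(x, 2L, function(col) rank(col, ties.method = "average") / length(col))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  if (length(x) == 0L) stopf("rank_normalize: empty vector")
  if (!all(is.finite(x)))
    stopf("rank_normalize: non-finite value at position %d",
          which(!is.finite(x))[1L])
  rank(x, ties.method = "average") / length(x)
}

#' Normalize discrete copy-number calls to the unit interval
#'
#' Maps copy-number alteration calls on the alphabet \{-2, -1, 0, 1, 2\}
#' onto the five-point grid \{0, 0.25, 0.5, 0.75, 1\} by the affine map
#' `(x + 2) / 4`.
#'
#' @param calls Numeric vector or matrix of CNA calls; every entry must be
#'   one of -2, -1, 0, 1, 2.
#' @return Same shape as `calls`, with values on the five-point grid.
#' @export
cna_normalize <- function(calls) {
  bad <- !(calls %in% c(-2, -1, 0, 1, 2)) | !is.finite(calls)
  if (any(bad)) {
    i <- which(bad)[1L]
    pos <- if (is.matrix(calls)) {
      rc <- arrayInd(i, dim(calls))
      sprintf("row %d, column %d", rc[1L], rc[2L])
    } else sprintf("position %d", i)
    stopf("cna_normalize: value %s at %s is outside {-2,-1,0,1,2}",
          format(calls[i]), pos)
  }
  (calls + 2) / 4
}

#' Construct an omics matrix
#'
#' Lightweight container for a feature-by-sample matrix of values in
#' `[0, 1]`, carrying one channel label (Exp, Meth, CNA, Mut, ...) per
#' feature row.
#'
#' @param values Numeric feature-by-sample matrix with unique rownames
#'   (feature ids) and colnames (sample ids), all values in `[0, 1]`.
#' @param channel Character vector of channel labels, one per row.
#' @return An `omics_matrix` object (a matrix with a `channel` attribute).
#' @export
omics_matrix <- function(values, channel) {
  values <- as.matrix(values)
  if (anyNA(values) || !all(is.finite(values)))
    stopf("omics_matrix: missing or non-finite values are not allowed")
  if (any(values < 0 | values > 1))
    stopf("omics_matrix: values must lie in [0, 1]")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("omics_matrix: values must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stopf("omics_matrix: duplicated feature ids")
  if (anyDuplicated(colnames(values)))
    stopf("omics_matrix: duplicated sample ids")
  if (length(channel) != nrow(values))
    stopf("omics_matrix: need one channel label per feature row")
  structure(values, channel = as.character(channel),
            class = c("omics_matrix", "matrix", "array"))
}

unclass_omics <- function(x) {
  attr(x, "channel") <- NULL
  class(x) <- NULL
  x
}

#' @export
print.omics_matrix <- function(x, ...) {
  tab <- table(attr(x, "channel"))
  cat(sprintf("omics_matrix: %d features x %d samples\n", nrow(x), ncol(x)))
  cat("channels:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Stack normalized omics channels into one input matrix
#'
#' Row-binds several already-normalized gene-by-sample matrices into a
#' single input matrix, prefixing feature ids with the channel name
#' (`"Exp:TP53"`) so the same gene may appear in several channels. All
#' channels must share an identical ordered sample set.
#'
#' @param channels Named list of numeric gene-by-sample matrices with
#'   values in `[0, 1]`; names are the channel labels.
#' @return An [omics_matrix()] with `sum(rows)` features.
#' @export
assemble_multiomics <- function(channels) {
  if (!is.list(channels) || length(channels) == 0L)
    stopf("assemble_multiomics: need a non-empty named list of channel matrices")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stopf("assemble_multiomics: every channel must be named")
  channels <- lapply(channels, as.matrix)
  samples <- colnames(channels[[1L]])
  if (is.null(samples)) stopf("assemble_multiomics: channels must have sample colnames")
  for (nm in names(channels)) {
    ci <- channels[[nm]]
    if (is.null(colnames(ci)) || !identical(colnames(ci), samples))
      stopf("assemble_multiomics: channel '%s' has a different ordered sample set", nm)
    if (is.null(rownames(ci)))
      stopf("assemble_multiomics: channel '%s' lacks feature rownames", nm)
  }
  stacked <- do.call(rbind, unname(channels))
  ids <- unlist(lapply(names(channels), function(nm)
    paste(nm, rownames(channels[[nm]]), sep = ":")), use.names = FALSE)
  if (anyDuplicated(ids))
    stopf("assemble_multiomics: duplicated feature id after prefixing: %s",
          ids[duplicated(ids)][1L])
  rownames(stacked) <- ids
  chan <- rep(names(channels), times = vapply(channels, nrow, 1L))
  omics_matrix(stacked, chan)
}
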