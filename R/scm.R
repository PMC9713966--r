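#' Construct a selectively connected mask
#'
#' A binary gene-by-node matrix gating the input-to-first-hidden-layer
#' weights of a gated network: 1 = connection enabled, 0 = weight forced
#' to zero. The fraction of zeros is the mask's sparsity.
#'
#' @param mask Matrix of 0/1 values (genes x nodes).
#' @return An `sc_mask` object with a `sparsity` attribute.
#' @export
sc_mask <- function(mask) {
  mask <- as.matrix(mask)
  if (!all(mask %in% c(0, 1))) stopf("sc_mask: entries must be 0 or 1")
  storage.mode(mask) <- "double"
  structure(mask, sparsity = mean(mask == 0),
            class = c("sc_mask", "matrix", "array"))
}

#' @export
print.sc_mask <- function(x, ...) {
  cat(sprintf("sc_mask: %d genes x %d nodes, sparsity %.3f\n",
              nrow(x), ncol(x), attr(x, "sparsity")))
  invisible(x)
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative input `X ~ W H` (Frobenius objective) with
#' Lee-Seung multiplicative updates. The rank `K` is set equal to the
#' width of the first hidden layer the mask will gate, so the gene-side
#' factor `W` assigns each gene a loading on each prospective node.
#'
#' @param X Non-negative gene-by-sample matrix (or [omics_matrix()]).
#' @param K Factorization rank; `1 <= K <= min(dim(X))`.
#' @param seed RNG seed for the random initialization.
#' @param max_iter Maximum number of multiplicative updates.
#' @param tol Relative improvement in reconstruction error below which
#'   iteration stops.
#' @return `nmf_loadings` list: `W` (genes x K), `H` (K x samples),
#'   `reconstruction_error` (Frobenius norm of the residual), `history`
#'   of errors, `iterations`, `K`.
#' @export
nmf_factorize <- function(X, K, seed = 1L, max_iter = 500L, tol = 1e-9) {
  X <- as_values(X)
  if (any(X < 0)) stopf("nmf_factorize: X has a negative entry")
  if (K < 1L || K > min(dim(X)))
    stopf("nmf_factorize: K = %d outside 1..min(dim(X)) = %d", K, min(dim(X)))
  n <- nrow(X); m <- ncol(X)
  eps <- 1e-10
  res <- with_seed(seed, {
    sc <- sqrt(mean(X) / K + eps)
    W <- matrix(stats::runif(n * K, min = 0.1, max = 1) * sc, n, K)
    H <- matrix(stats::runif(K * m, min = 0.1, max = 1) * sc, K, m)
    err <- numeric(0)
    prev <- Inf
    it <- 0L
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, X) / (crossprod(W, W %*% H) + eps))
      W <- W * ((X %*% t(H)) / (W %*% tcrossprod(H, H) + eps))
      e <- sqrt(sum((X - W %*% H)^2))
      err <- c(err, e)
      if (is.finite(prev) && prev - e < tol * max(prev, eps)) break
      prev <- e
    }
    list(W = W, H = H, err = err, it = it)
  })
  rownames(res$W) <- rownames(X)
  colnames(res$H) <- colnames(X)
  structure(list(W = res$W, H = res$H,
                 reconstruction_error = res$err[length(res$err)],
                 history = res$err, iterations = res$it, K = K),
            class = "nmf_loadings")
}

#' @export
print.nmf_loadings <- function(x, ...) {
  cat(sprintf("nmf_loadings: %d genes, K = %d, %d iterations, error %.4g\n",
              nrow(x$W), x$K, x$iterations, x$reconstruction_error))
  invisible(x)
}

#' Binarize loadings into a selectively connected mask
#'
#' Applies one global cutoff at the `target_sparsity` quantile of all
#' entries: the `round(target_sparsity * genes * K)` smallest entries are
#' disabled (0), the rest enabled (1). Ties are broken by stable
#' row-major order so the achieved zero count is exact. A single global
#' cutoff (rather than per-node or per-gene) makes the sparsity exactly
#' controllable and reproducible.
#'
#' @param L An `nmf_loadings` object (its `W` is used) or a numeric
#'   gene-by-node matrix of loadings.
#' @param target_sparsity Fraction of entries to disable, in `[0, 1)`.
#' @return An [sc_mask()]. Genes left with no enabled connection trigger
#'   a warning: they become dead inputs.
#' @export
binarize_loadings <- function(L, target_sparsity) {
  W <- if (inherits(L, "nmf_loadings")) L$W else as.matrix(L)
  if (!is.numeric(target_sparsity) || target_sparsity < 0 || target_sparsity >= 1)
    stopf("binarize_loadings: target_sparsity must be in [0, 1)")
  nzero <- round(target_sparsity * length(W))
  mask <- matrix(1, nrow(W), ncol(W), dimnames = dimnames(W))
  if (nzero > 0L) {
    rm_index <- as.vector((row(W) - 1L) * ncol(W) + col(W))  # row-major position
    ord <- order(as.vector(W), rm_index)
    mask[ord[seq_len(nzero)]] <- 0
  }
  dead <- rowSums(mask) == 0
  if (any(dead))
    warnf("binarize_loadings: %d gene(s) have no enabled connection (dead inputs)",
          sum(dead))
  sc_mask(mask)
}

#' Pearson correlation of pairwise gene distances
#'
#' Correlates the vectors of all pairwise Euclidean distances between
#' gene rows of `A` and of `B` (length `G*(G-1)/2`). Used both to select
#' the mask sparsity (input matrix vs candidate mask) and as a training
#' diagnostic (input matrix vs effective first-layer weights): a high
#' value means similar genes connect to similar nodes.
#'
#' @param A,B Matrices with the same genes in the same row order (their
#'   column counts may differ).
#' @return Pearson r in `[-1, 1]`, or `NA` with a warning when either
#'   distance vector has zero variance.
#' @export
gene_distance_correlation <- function(A, B) {
  A <- as_values(A); B <- as_values(B)
  if (nrow(A) != nrow(B))
    stopf("gene_distance_correlation: gene sets differ (%d vs %d rows)",
          nrow(A), nrow(B))
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stopf("gene_distance_correlation: gene row order differs")
  if (nrow(A) < 3L) stopf("gene_distance_correlation: need at least 3 genes")
  da <- as.vector(stats::dist(A))
  db <- as.vector(stats::dist(B))
  if (stats::sd(da) == 0 || stats::sd(db) == 0) {
    warnf("gene_distance_correlation: zero-variance distance vector; returning NA")
    return(NA_real_)
  }
  stats::cor(da, db)
}

#' Select the mask sparsity from a candidate grid
#'
#' For each candidate sparsity the loadings are binarized and the
#' gene-distance correlation between the input matrix and the candidate
#' mask is computed. The chosen sparsity is the largest candidate whose
#' correlation has not dropped more than `drop_tolerance` (relative)
#' below the best over the grid - i.e. the largest sparsity that does
#' not make the correlation collapse.
#'
#' @param X Input gene-by-sample matrix (or [omics_matrix()]).
#' @param L `nmf_loadings` (or loading matrix) over the same genes.
#' @param grid Increasing candidate sparsities in `[0, 1)`.
#' @param drop_tolerance Allowed relative drop from the maximum
#'   correlation (default 0.05).
#' @return `sparsity_profile` list: `grid`, `correlations`, `chosen`.
#' @export
select_sparsity <- function(X, L, grid = seq(0.1, 0.9, by = 0.1),
                            drop_tolerance = 0.05) {
  if (length(grid) == 0L || any(grid < 0 | grid >= 1))
    stopf("select_sparsity: grid must be non-empty within [0, 1)")
  grid <- sort(grid)
  X <- as_values(X)
  cors <- vapply(grid, function(s) {
    mask <- suppressWarnings(binarize_loadings(L, s))
    suppressWarnings(gene_distance_correlation(X, mask))
  }, numeric(1))
  if (all(is.na(cors)))
    stopf("select_sparsity: all candidates yield undefined correlation")
  rmax <- max(cors, na.rm = TRUE)
  ok <- !is.na(cors) & cors >= (1 - drop_tolerance) * rmax
  chosen <- max(grid[ok])
  structure(list(grid = grid, correlations = cors, chosen = chosen),
            class = "sparsity_profile")
}

#' @export
print.sparsity_profile <- function(x, ...) {
  cat("sparsity_profile (chosen =", x$chosen, ")\n")
  print(data.frame(sparsity = x$grid, r = round(x$correlations, 4)))
  invisible(x)
}

#' Build a selectively connected mask from data by NMF
#'
#' Convenience wrapper: factorize the input at rank `K`, pick the
#' sparsity on a grid (unless given), and binarize the gene-side
#' loadings.
#'
#' @inheritParams nmf_factorize
#' @param sparsity Fixed sparsity in `[0, 1)`, or `NULL` to select via
#'   [select_sparsity()].
#' @param grid,drop_tolerance Passed to [select_sparsity()] when
#'   `sparsity` is `NULL`.
#' @param max_iter NMF iteration cap.
#' @return An [sc_mask()]; the `profile` attribute carries the
#'   [select_sparsity()] result when the sparsity was data-driven.
#' @export
build_scm <- function(X, K, sparsity = NULL, grid = seq(0.1, 0.9, by = 0.1),
                      drop_tolerance = 0.05, seed = 1L, max_iter = 300L) {
  L <- nmf_factorize(X, K, seed = seed, max_iter = max_iter)
  profile <- NULL
  if (is.null(sparsity)) {
    profile <- select_sparsity(X, L, grid = grid, drop_tolerance = drop_tolerance)
    sparsity <- profile$chosen
  }
  mask <- binarize_loadings(L, sparsity)
  attr(mask, "profile") <- profile
  mask
}
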