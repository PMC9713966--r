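#' Train a single-bottleneck autoencoder
#'
#' Fits `X ~ decode(relu(encode(X)))` by full-batch gradient descent on
#' the mean squared reconstruction error. The bottleneck width `K` is
#' the width of the first hidden layer the resulting mask will gate.
#' The hidden activation is the rectifier; the output is linear.
#'
#' @param X Gene-by-sample matrix (or [omics_matrix()]).
#' @param K Bottleneck width, `K < nrow(X)`.
#' @param iterations Gradient steps (default 30000, matching the long
#'   schedule used for interaction-prior masks; reduce for exploration).
#' @param lr Learning rate.
#' @param seed RNG seed for Xavier initialization.
#' @param log_every Record the loss every this many iterations.
#' @return `autoencoder_model` list: encoder `We` (genes x K), `be`,
#'   decoder `Wd` (K x genes), `bd`, `K`, `iterations`, loss `history`.
#' @export
train_autoencoder <- function(X, K, iterations = 30000L, lr = 0.01, seed = 1L,
                              log_every = max(1L, iterations %/% 200L)) {
  X <- as_values(X)
  n <- nrow(X); m <- ncol(X)
  if (K >= n) stopf("train_autoencoder: K must be smaller than the input width")
  if (iterations < 1L) stopf("train_autoencoder: iterations must be >= 1")
  init <- with_seed(seed, list(
    We = matrix(stats::rnorm(n * K, sd = sqrt(2 / (n + K))), n, K),
    Wd = matrix(stats::rnorm(K * n, sd = sqrt(2 / (K + n))), K, n)
  ))
  We <- init$We; Wd <- init$Wd
  be <- numeric(K); bd <- numeric(n)
  history <- numeric(0)
  for (it in seq_len(iterations)) {
    Z <- crossprod(We, X) + be          # K x m
    A <- pmax(Z, 0)
    Xhat <- crossprod(Wd, A) + bd       # n x m
    R <- Xhat - X
    loss <- sum(R^2) / (2 * m)
    if (!is.finite(loss))
      stopf("train_autoencoder: diverged (non-finite loss) at iteration %d", it)
    if (it %% log_every == 0L) history <- c(history, loss)
    gWd <- A %*% t(R) / m
    gbd <- rowMeans(R)
    dA <- (Wd %*% R) * (Z > 0)
    gWe <- X %*% t(dA) / m
    gbe <- rowMeans(dA)
    Wd <- Wd - lr * gWd; bd <- bd - lr * gbd
    We <- We - lr * gWe; be <- be - lr * gbe
  }
  rownames(We) <- rownames(X)
  structure(list(We = We, be = be, Wd = Wd, bd = bd, K = K,
                 iterations = iterations, history = history),
            class = "autoencoder_model")
}

#' @export
print.autoencoder_model <- function(x, ...) {
  cat(sprintf("autoencoder_model: %d genes -> %d bottleneck nodes, %d iterations\n",
              nrow(x$We), x$K, x$iterations))
  invisible(x)
}

#' Derive a selectively connected mask from autoencoder weights
#'
#' Thresholds the absolute gene-to-bottleneck encoder weights at the
#' global `target_sparsity` quantile, exactly as [binarize_loadings()]
#' does for NMF loadings: genes that drive a bottleneck node strongly
#' stay connected to the corresponding first-layer node.
#'
#' @param model A trained [train_autoencoder()] model.
#' @param target_sparsity Fraction of entries to disable, in `[0, 1)`.
#' @return An [sc_mask()] of dimension genes x K.
#' @export
autoencoder_mask <- function(model, target_sparsity) {
  if (!inherits(model, "autoencoder_model"))
    stopf("autoencoder_mask: 'model' must be a trained autoencoder_model")
  binarize_loadings(abs(model$We), target_sparsity)
}
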