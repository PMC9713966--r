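.selu_lambda <- 1.05070098736
.selu_alpha <- 1.67326324235
.exp_clip <- 30

#' Scaled exponential linear unit
#'
#' `selu(x) = lambda * x` for `x > 0` and
#' `lambda * alpha * (exp(x) - 1)` for `x <= 0`, with the fixed
#' self-normalizing constants `lambda = 1.05070098736` and
#' `alpha = 1.67326324235`. Used in every hidden layer; its self-
#' normalizing property keeps activations from exploding or vanishing
#' in deep stacks.
#'
#' @param x Numeric vector or matrix.
#' @return `selu`: the activation; `selu_grad`: its derivative.
#' @export
selu <- function(x) {
  .selu_lambda * (pmax(x, 0) + .selu_alpha * (exp(pmin(x, 0)) - 1))
}

#' @rdname selu
#' @export
selu_grad <- function(x) {
  .selu_lambda * ((x > 0) + (x <= 0) * .selu_alpha * exp(pmin(x, 0)))
}

#' Xavier initialization of network parameters
#'
#' Weights from layer `l` to `l+1` are drawn i.i.d.
#' `Normal(0, 2 / (n_l + n_{l+1}))`; all biases start at zero.
#'
#' @param layer_sizes Integer vector `(n_0, ..., n_L)` of node counts,
#'   input layer first, output layer last; at least two layers, all
#'   positive.
#' @param seed RNG seed.
#' @return `network_params` list with `weights` (list of `n_l x n_{l+1}`
#'   matrices), `biases` (list of zero vectors), `layer_sizes`.
#' @export
xavier_init <- function(layer_sizes, seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L) stopf("xavier_init: need at least 2 layers")
  if (any(layer_sizes < 1L)) stopf("xavier_init: layer sizes must be positive")
  L <- length(layer_sizes) - 1L
  weights <- with_seed(seed, lapply(seq_len(L), function(l) {
    nl <- layer_sizes[l]; nn <- layer_sizes[l + 1L]
    matrix(stats::rnorm(nl * nn, sd = sqrt(2 / (nl + nn))), nl, nn)
  }))
  biases <- lapply(seq_len(L), function(l) numeric(layer_sizes[l + 1L]))
  structure(list(weights = weights, biases = biases, layer_sizes = layer_sizes),
            class = "network_params")
}

#' Training configuration for a gated network
#'
#' @param loss One of `"quadratic"` (SF2 regression), `"nlpl"` (negative
#'   log partial likelihood) or `"pqc"` (partial quadratic cost).
#' @param output_activation `"sigmoid"` or `"exp"`. Defaults to the
#'   conventional pairing: sigmoid for the quadratic cost (outputs in
#'   `(0,1)` like SF2), exp for the survival costs (positive scores /
#'   times). Mismatched pairings are rejected.
#' @param learning_rate Fixed step size for full-batch gradient descent.
#' @param iterations Number of gradient steps.
#' @param seed RNG seed used for initialization.
#' @param log_every Record the cost every this many iterations.
#' @param diag_every If positive, record the gene-distance correlation
#'   between the input and the effective first-layer weights every this
#'   many iterations (and at initialization) - the training diagnostic
#'   showing similar genes acquiring similar node connections.
#' @return `net_config` list.
#' @export
net_config <- function(loss = c("quadratic", "nlpl", "pqc"),
                       output_activation = NULL,
                       learning_rate = 0.01, iterations = 2000L, seed = 1L,
                       log_every = 10L, diag_every = 0L) {
  loss <- match.arg(loss)
  default_act <- if (loss == "quadratic") "sigmoid" else "exp"
  output_activation <- output_activation %||% default_act
  output_activation <- match.arg(output_activation, c("sigmoid", "exp"))
  if (loss == "quadratic" && output_activation != "sigmoid")
    stopf("net_config: the quadratic cost pairs with the sigmoid output")
  if (loss != "quadratic" && output_activation != "exp")
    stopf("net_config: survival costs pair with the exp output")
  structure(list(loss = loss, output_activation = output_activation,
                 learning_rate = learning_rate,
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 log_every = as.integer(log_every),
                 diag_every = as.integer(diag_every)),
            class = "net_config")
}

#' Forward pass through a gated network
#'
#' The first-layer weights are multiplied elementwise by the mask before
#' use, hidden layers apply [selu()], and the single output node applies
#' the sigmoid or (clipped) exp activation.
#'
#' @param params A [xavier_init()] parameter set.
#' @param mask An [sc_mask()] of dimension `n_0 x n_1`, or `NULL` for a
#'   fully connected network.
#' @param X Input matrix, `n_0` features x m samples.
#' @param output_activation `"sigmoid"` or `"exp"`.
#' @return List with `h` (numeric outputs, length m), cached `A`
#'   (activations per layer), `Z` (pre-activations), and `clipped`
#'   (whether the exp output hit its overflow guard).
#' @export
net_forward <- function(params, mask, X, output_activation) {
  X <- as_values(X)
  if (!is.null(mask)) mask <- as_values(mask)
  W <- params$weights; B <- params$biases
  L <- length(W)
  if (nrow(X) != nrow(W[[1L]]))
    stopf("net_forward: X has %d rows but the input layer expects %d",
          nrow(X), nrow(W[[1L]]))
  if (!is.null(mask) && !identical(dim(mask), dim(W[[1L]])))
    stopf("net_forward: mask dimensions do not match the first weight layer")
  A <- vector("list", L + 1L); Z <- vector("list", L + 1L)
  A[[1L]] <- X
  clipped <- FALSE
  for (l in seq_len(L)) {
    Wl <- W[[l]]
    if (l == 1L && !is.null(mask)) Wl <- Wl * mask
    Z[[l + 1L]] <- crossprod(Wl, A[[l]]) + B[[l]]
    if (l < L) {
      A[[l + 1L]] <- selu(Z[[l + 1L]])
    } else {
      A[[l + 1L]] <- switch(output_activation,
        sigmoid = stats::plogis(Z[[l + 1L]]),
        exp = {
          clipped <- any(Z[[l + 1L]] > .exp_clip)
          exp(pmin(Z[[l + 1L]], .exp_clip))
        },
        stopf("net_forward: unknown output activation '%s'", output_activation))
    }
  }
  list(h = as.numeric(A[[L + 1L]]), A = A, Z = Z, clipped = clipped)
}

#' Quadratic cost
#'
#' `J = (1 / 2m) * sum((h_i - y_i)^2)` with no regularization term.
#'
#' @param h Model outputs.
#' @param y Targets (SF2 values in `[0, 1]`).
#' @param m Sample count in the normalizer (defaults to `length(h)`).
#' @return Scalar cost.
#' @export
quadratic_cost <- function(h, y, m = length(h)) {
  if (length(h) != length(y)) stopf("quadratic_cost: length mismatch")
  sum((h - y)^2) / (2 * m)
}

#' Negative log partial likelihood cost
#'
#' Cox-style partial likelihood over event risk sets:
#' `J = -sum over events i of (h_i - log sum_{j: T_j >= T_i} exp(h_j))`.
#' Computed with max-subtraction for numerical stability. Adding a
#' constant to all scores leaves the value unchanged.
#'
#' @param h Model outputs (risk scores; larger = higher risk).
#' @param surv A [survival_data()] object.
#' @return Scalar cost; 0 with a warning when there are no events.
#' @export
nlpl_cost <- function(h, surv) {
  surv <- as_survival(surv)
  if (length(h) != length(surv$time)) stopf("nlpl_cost: length mismatch")
  vg <- nlpl_value_grad(h, surv)
  if (vg$empty) warnf("nlpl_cost: no events; empty sum, returning 0")
  vg$value
}

nlpl_value_grad <- function(h, surv) {
  T <- surv$time; E <- surv$event
  ev <- which(E == 1)
  if (length(ev) == 0L)
    return(list(value = 0, grad = rep(0, length(h)), empty = TRUE))
  a <- max(h)
  eh <- exp(h - a)
  riskmat <- outer(T[ev], T, "<=")          # [i, k]: is k in R(T_i)?
  S <- as.numeric(riskmat %*% eh)           # shifted risk-set sums
  value <- -(sum(h[ev]) - sum(a + log(S)))
  grad <- -(E == 1) + eh * as.numeric(crossprod(riskmat, 1 / S))
  list(value = value, grad = grad, empty = FALSE)
}

#' Partial quadratic cost
#'
#' Squared-error survival loss over the active set
#' `S = {events} union {censored with h_i < T_i}`:
#' `J = (1 / 2m) * sum_{i in S} (h_i - T_i)^2`. A censored sample whose
#' predicted time is at least its censoring time is consistent with its
#' observation and contributes nothing; this is what makes the cost
#' censoring-aware while staying O(m) per evaluation.
#'
#' @param h Model outputs on the predicted-time scale.
#' @param surv A [survival_data()] object.
#' @param m Sample count in the normalizer (defaults to `length(h)`).
#' @return Scalar cost (non-negative).
#' @export
pqc_cost <- function(h, surv, m = length(h)) {
  surv <- as_survival(surv)
  if (length(h) != length(surv$time)) stopf("pqc_cost: length mismatch")
  pqc_value_grad(h, surv, m)$value
}

pqc_value_grad <- function(h, surv, m = length(h)) {
  T <- surv$time; E <- surv$event
  active <- E == 1 | h < T
  r <- h - T
  grad <- numeric(length(h))
  grad[active] <- r[active] / m
  list(value = sum(r[active]^2) / (2 * m), grad = grad)
}

cost_value_grad <- function(loss, h, targets, m) {
  switch(loss,
    quadratic = {
      if (length(h) != length(targets)) stopf("quadratic cost: length mismatch")
      list(value = sum((h - targets)^2) / (2 * m), grad = (h - targets) / m)
    },
    nlpl = nlpl_value_grad(h, targets)[c("value", "grad")],
    pqc = pqc_value_grad(h, targets, m),
    stopf("unknown loss '%s'", loss))
}

net_backprop <- function(params, mask, fw, dJdh, output_activation) {
  W <- params$weights
  L <- length(W)
  h <- fw$h
  zL <- as.numeric(fw$Z[[L + 1L]])
  dhdz <- switch(output_activation,
    sigmoid = h * (1 - h),
    exp = h * (zL <= .exp_clip))          # clip region has zero slope
  delta <- matrix(dJdh * dhdz, nrow = 1L)
  gW <- vector("list", L); gB <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- fw$A[[l]] %*% t(delta)
    gB[[l]] <- rowSums(delta)
    if (l > 1L) delta <- (W[[l]] %*% delta) * selu_grad(fw$Z[[l]])
  }
  if (!is.null(mask)) gW[[1L]] <- gW[[1L]] * mask
  list(weights = gW, biases = gB)
}

#' One full-batch gradient-descent step
#'
#' Computes the selected cost and its analytic gradient by
#' backpropagation, multiplies the first-layer gradient by the mask so
#' disabled weights stay exactly zero, and takes one fixed-step update.
#'
#' @param params `network_params`.
#' @param mask [sc_mask()] or `NULL`.
#' @param X Input matrix (features x samples).
#' @param targets Numeric SF2 vector (quadratic) or [survival_data()]
#'   (nlpl/pqc).
#' @param config A [net_config()].
#' @return List with updated `params` and the pre-step `cost`.
#' @export
train_step <- function(params, mask, X, targets, config) {
  X <- as_values(X)
  if (!is.null(mask)) mask <- as_values(mask)
  fw <- net_forward(params, mask, X, config$output_activation)
  cg <- cost_value_grad(config$loss, fw$h, targets, ncol(X))
  if (!is.finite(cg$value))
    stopf("train_step: non-finite cost")
  gr <- net_backprop(params, mask, fw, cg$grad, config$output_activation)
  if (any(!vapply(gr$weights, function(g) all(is.finite(g)), logical(1))))
    stopf("train_step: non-finite gradient")
  lr <- config$learning_rate
  for (l in seq_along(params$weights)) {
    params$weights[[l]] <- params$weights[[l]] - lr * gr$weights[[l]]
    params$biases[[l]] <- params$biases[[l]] - lr * gr$biases[[l]]
  }
  if (!is.null(mask)) params$weights[[1L]] <- params$weights[[1L]] * mask
  list(params = params, cost = cg$value)
}

#' Fit a gated network
#'
#' Runs mask-preserving full-batch gradient descent for
#' `config$iterations` steps. For survival losses the follow-up times
#' are divided by the maximum training time before fitting (the factor
#' is stored as `time_scale` and predictions are rescaled back); raw
#' day-scale times would overflow the exp output.
#'
#' @param X Input matrix (features x samples) or [omics_matrix()].
#' @param targets SF2 vector in `[0, 1]` (quadratic loss) or
#'   [survival_data()] (nlpl/pqc).
#' @param layer_sizes Full node counts `(n_0, ..., n_L)`;
#'   `n_0 = nrow(X)` and `n_L = 1`.
#' @param mask [sc_mask()] of dimension `n_0 x n_1`, or `NULL` for full
#'   connection.
#' @param config A [net_config()].
#' @return `gated_net` model: `params`, `mask`, `config`, `layer_sizes`,
#'   `history` (data frame iteration/cost), `diag` (data frame
#'   iteration/r when `diag_every > 0`), `time_scale`, `task`,
#'   `prediction_type` (`"sf2"`, `"time"`, or `"risk"`), `feature_ids`.
#' @export
fit_network <- function(X, targets, layer_sizes, mask = NULL,
                        config = net_config()) {
  X <- as_values(X)
  layer_sizes <- as.integer(layer_sizes)
  if (layer_sizes[1L] != nrow(X))
    stopf("fit_network: layer_sizes[1] = %d but X has %d features",
          layer_sizes[1L], nrow(X))
  if (layer_sizes[length(layer_sizes)] != 1L)
    stopf("fit_network: the output layer must have exactly one node")
  is_surv <- inherits(targets, "survival_data")
  if (config$loss == "quadratic") {
    if (is_surv) stopf("fit_network: the quadratic loss needs numeric SF2 targets")
    if (length(targets) != ncol(X)) stopf("fit_network: target length mismatch")
    task <- "sf2"; time_scale <- NA_real_
    fit_targets <- targets
  } else {
    if (!is_surv) stopf("fit_network: survival losses need survival_data targets")
    if (length(targets$time) != ncol(X)) stopf("fit_network: target length mismatch")
    task <- "survival"
    time_scale <- max(targets$time)
    fit_targets <- survival_data(targets$time / time_scale, targets$event)
  }
  if (!is.null(mask) && !identical(dim(mask), c(layer_sizes[1L], layer_sizes[2L])))
    stopf("fit_network: mask must be %d x %d", layer_sizes[1L], layer_sizes[2L])

  mask_v <- if (is.null(mask)) NULL else as_values(mask)
  params <- xavier_init(layer_sizes, seed = config$seed)
  if (!is.null(mask_v)) params$weights[[1L]] <- params$weights[[1L]] * mask_v

  hist_it <- integer(0); hist_cost <- numeric(0)
  diag_it <- integer(0); diag_r <- numeric(0)
  record_diag <- function(it, p) {
    W1 <- p$weights[[1L]]
    if (!is.null(mask_v)) W1 <- W1 * mask_v
    r <- suppressWarnings(gene_distance_correlation(X, W1))
    diag_it <<- c(diag_it, it); diag_r <<- c(diag_r, r)
  }
  if (config$diag_every > 0L) record_diag(0L, params)
  clipped <- FALSE
  for (it in seq_len(config$iterations)) {
    step <- tryCatch(train_step(params, mask_v, X, fit_targets, config),
                     error = function(e)
                       stopf("fit_network: %s (iteration %d)", conditionMessage(e), it))
    params <- step$params
    if (it %% config$log_every == 0L) {
      hist_it <- c(hist_it, it); hist_cost <- c(hist_cost, step$cost)
    }
    if (config$diag_every > 0L &&
        (it %% config$diag_every == 0L || it == config$iterations))
      record_diag(it, params)
  }
  prediction_type <- switch(config$loss, quadratic = "sf2",
                            pqc = "time", nlpl = "risk")
  structure(list(params = params, mask = mask, config = config,
                 layer_sizes = layer_sizes,
                 history = data.frame(iteration = hist_it, cost = hist_cost),
                 diag = if (config$diag_every > 0L)
                   data.frame(iteration = diag_it, r = diag_r) else NULL,
                 time_scale = time_scale, task = task,
                 prediction_type = prediction_type,
                 feature_ids = rownames(X)),
            class = "gated_net")
}

#' @export
print.gated_net <- function(x, ...) {
  cat(sprintf("gated_net: layers (%s), %s loss, %d iterations, %s\n",
              paste(x$layer_sizes, collapse = ", "), x$config$loss,
              x$config$iterations,
              if (is.null(x$mask)) "fully connected"
              else sprintf("mask sparsity %.3f", attr(x$mask, "sparsity"))))
  invisible(x)
}

#' Predict from a fitted gated network
#'
#' @param object A `gated_net` model.
#' @param X Input matrix with the model's features as rows.
#' @param ... Unused.
#' @return Numeric predictions: SF2 in `(0, 1)` for the quadratic loss,
#'   predicted times on the original scale for PQC (rescaled by the
#'   stored `time_scale`), positive risk scores for NLPL (larger =
#'   higher risk).
#' @export
predict.gated_net <- function(object, X, ...) {
  h <- net_forward(object$params, object$mask, X,
                   object$config$output_activation)$h
  if (identical(object$prediction_type, "time")) h <- h * object$time_scale
  h
}

# Predictions on the predicted-time orientation used by the C-index:
# larger value = longer expected survival.
predicted_time_orientation <- function(model, X) {
  h <- predict(model, X)
  if (identical(model$prediction_type, "risk")) -h else h
}

#' Structural per-iteration operation counts of the survival costs
#'
#' Counts the elementary arithmetic operations (adds, multiplies, exp,
#' log, comparisons) one evaluation of each survival cost needs for the
#' given follow-up data. The partial quadratic cost is linear in the
#' sample count, while the partial-likelihood cost pays one exp per
#' sample plus the size of every event's risk set, so its count grows
#' with the number of events times the risk-set sizes.
#'
#' @param surv A [survival_data()] object.
#' @return Named list with `pqc` and `nlpl` counts.
#' @export
survival_cost_op_counts <- function(surv) {
  surv <- as_survival(surv)
  T <- surv$time; E <- surv$event
  m <- length(T)
  ev <- which(E == 1)
  # PQC: per sample one comparison and one event test to build the
  # active set, at most one subtract + square + add each; plus scaling.
  pqc <- 2 * m + 3 * m + 2
  # NLPL: one exp per sample, then per event: |R(T_i)| adds for the
  # risk-set sum, one log, two adds.
  risk_sizes <- vapply(ev, function(i) sum(T >= T[i]), numeric(1))
  nlpl <- m + sum(risk_sizes) + 3 * length(ev)
  list(pqc = as.numeric(pqc), nlpl = as.numeric(nlpl))
}
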