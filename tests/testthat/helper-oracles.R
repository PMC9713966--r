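# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: the gradient oracle is plain central finite
# differences on the forward cost, the concordance oracle is an explicit
# double loop over all pairs.

flatten_params <- function(p) c(unlist(p$weights), unlist(p$biases))

unflatten_params <- function(v, p) {
  i <- 0L
  for (l in seq_along(p$weights)) {
    k <- length(p$weights[[l]])
    p$weights[[l]][] <- v[i + seq_len(k)]; i <- i + k
  }
  for (l in seq_along(p$biases)) {
    k <- length(p$biases[[l]])
    p$biases[[l]][] <- v[i + seq_len(k)]; i <- i + k
  }
  p
}

cost_at <- function(params, mask, X, targets, config) {
  fw <- net_forward(params, mask, X, config$output_activation)
  switch(config$loss,
    quadratic = quadratic_cost(fw$h, targets),
    nlpl = nlpl_cost(fw$h, targets),
    pqc = pqc_cost(fw$h, targets))
}

numeric_gradient <- function(params, mask, X, targets, config, h = 1e-6) {
  v0 <- flatten_params(params)
  vapply(seq_along(v0), function(i) {
    vp <- v0; vp[i] <- vp[i] + h
    vm <- v0; vm[i] <- vm[i] - h
    (cost_at(unflatten_params(vp, params), mask, X, targets, config) -
       cost_at(unflatten_params(vm, params), mask, X, targets, config)) / (2 * h)
  }, numeric(1))
}

analytic_gradient <- function(params, mask, X, targets, config) {
  fw <- net_forward(params, mask, X, config$output_activation)
  cg <- genegate:::cost_value_grad(config$loss, fw$h, targets, ncol(X))
  gr <- genegate:::net_backprop(params, mask, fw, cg$grad,
                                config$output_activation)
  c(unlist(gr$weights), unlist(gr$biases))
}

# Brute-force Harrell concordance: enumerate every ordered pair.
c_index_bruteforce <- function(pred, time, event) {
  n <- length(pred)
  num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (pred[i] < pred[j]) num <- num + 1
      else if (pred[i] == pred[j]) num <- num + 0.5
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Mann-Whitney AUC of scores for separating TRUE from FALSE labels.
rank_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Degree-matched random mask: permute each gene row independently, so
# every gene keeps its number of enabled connections.
shuffle_mask_rows <- function(mask, seed) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  genegate:::with_seed(seed, {
    for (i in seq_len(nrow(m))) m[i, ] <- sample(m[i, ])
    m
  })
}
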