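test_that("Xavier initialization has the prescribed variance and zero biases", {
  p <- xavier_init(c(288, 61, 1), seed = 3)
  expect_equal(dim(p$weights[[1]]), c(288L, 61L))
  # empirical variance over the 17,568 draws within 5% of 2 / (288 + 61)
  expect_lt(abs(var(as.vector(p$weights[[1]])) - 2 / 349), 0.05 * 2 / 349)
  expect_true(all(p$biases[[1]] == 0))
  expect_true(all(p$biases[[2]] == 0))
  expect_identical(p, xavier_init(c(288, 61, 1), seed = 3))
  expect_error(xavier_init(c(10, 0, 1)), "positive")
  expect_error(xavier_init(5), "2 layers")
})

test_that("SELU matches its closed form and the derivative agrees with finite differences", {
  lambda <- 1.05070098736
  alpha <- 1.67326324235
  expect_identical(selu(0), 0)
  expect_identical(selu(1), lambda)
  expect_equal(selu(-10), lambda * alpha * (exp(-10) - 1))
  # continuity at 0 from both sides
  expect_lt(abs(selu(1e-9) - selu(-1e-9)), 1e-8)
  for (x in c(-3, -0.5, 0.4, 2)) {
    fd <- (selu(x + 1e-7) - selu(x - 1e-7)) / 2e-7
    expect_lt(abs(fd - selu_grad(x)), 1e-6)
  }
})

test_that("forward pass honours the gating contract", {
  set.seed(31)
  X <- matrix(runif(10 * 6), 10, 6)
  params <- xavier_init(c(10, 4, 1), seed = 1)
  ones <- sc_mask(matrix(1, 10, 4))
  expect_identical(net_forward(params, ones, X, "sigmoid")$h,
                   net_forward(params, NULL, X, "sigmoid")$h)
  # zero parameters with sigmoid output predict 0.5 everywhere
  zero <- params
  for (l in 1:2) zero$weights[[l]][] <- 0
  expect_equal(net_forward(zero, NULL, X, "sigmoid")$h, rep(0.5, 6))
  # a gene with an all-zero mask row is a dead input
  mask <- matrix(1, 10, 4); mask[3, ] <- 0
  h0 <- net_forward(params, sc_mask(mask), X, "sigmoid")$h
  X2 <- X; X2[3, ] <- X2[3, ] + 100
  expect_identical(net_forward(params, sc_mask(mask), X2, "sigmoid")$h, h0)
  expect_error(net_forward(params, NULL, X[1:9, ], "sigmoid"), "rows")
})

test_that("quadratic cost matches hand arithmetic", {
  expect_equal(quadratic_cost(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(quadratic_cost(0.5, 0.3), 0.02)
  h <- c(0.1, 0.9); y <- c(0.4, 0.5)
  expect_equal(quadratic_cost(h, y),
               mean(c(quadratic_cost(h[1], y[1]), quadratic_cost(h[2], y[2]))))
  expect_error(quadratic_cost(1:3, 1:2), "mismatch")
})

test_that("NLPL matches the risk-set enumeration and is shift invariant", {
  s <- survival_data(c(1, 2), c(1, 1))
  h <- c(0.3, -0.4)
  manual <- -((h[1] - log(exp(h[1]) + exp(h[2]))) + (h[2] - log(exp(h[2]))))
  expect_equal(nlpl_cost(h, s), manual)
  expect_warning(z <- nlpl_cost(h, survival_data(c(1, 2), c(0, 0))), "no events")
  expect_equal(z, 0)
  set.seed(32)
  for (i in 1:10) {
    n <- 12
    s <- survival_data(rexp(n) + 0.01, rbinom(n, 1, 0.6))
    h <- rnorm(n)
    expect_equal(nlpl_cost(h, s), nlpl_cost(h + 5.3, s))
  }
})

test_that("PQC drops censored samples predicted beyond their censoring time", {
  expect_equal(pqc_cost(3, survival_data(3, 1)), 0)
  # censored with prediction past the censoring time contributes nothing
  expect_equal(pqc_cost(5, survival_data(4, 0)), 0)
  # event (h=2, T=3) in; censored (h=5, T=4) out: (1/4)(2-3)^2
  expect_equal(pqc_cost(c(2, 5), survival_data(c(3, 4), c(1, 0))), 0.25)
  # censored under-prediction does contribute
  expect_equal(pqc_cost(2, survival_data(4, 0)), 2)
  set.seed(33)
  for (i in 1:10)
    expect_gte(pqc_cost(rnorm(8, 1), survival_data(rexp(8) + 0.1, rbinom(8, 1, 0.5))), 0)
})

test_that("analytic gradients match central finite differences for all three losses", {
  set.seed(42)
  n0 <- 20; m <- 12
  X <- matrix(runif(n0 * m), n0, m)
  mask <- sc_mask(matrix(rbinom(n0 * 8, 1, 0.5), n0, 8))
  params <- xavier_init(c(20, 8, 4, 1), seed = 7)
  params$weights[[1]] <- params$weights[[1]] * unclass(mask)[, ]
  for (loss in c("quadratic", "nlpl", "pqc")) {
    cfg <- net_config(loss = loss)
    targets <- if (loss == "quadratic") runif(m)
               else survival_data(runif(m, 0.1, 1), rbinom(m, 1, 0.7))
    ga <- analytic_gradient(params, mask, X, targets, cfg)
    gn <- numeric_gradient(params, mask, X, targets, cfg)
    free <- abs(gn) > 1e-10  # masked first-layer entries have zero gradient
    expect_lt(max(abs(ga[free] - gn[free]) / abs(gn[free])), 1e-5)
    expect_true(all(abs(ga[!free]) < 1e-8))
  }
})

test_that("training preserves the mask and a zero learning rate freezes parameters", {
  set.seed(43)
  X <- matrix(runif(12 * 20), 12, 20)
  y <- runif(20)
  mask <- sc_mask(matrix(rbinom(12 * 5, 1, 0.5), 12, 5))
  cfg <- net_config("quadratic", learning_rate = 0.05, iterations = 1)
  params <- xavier_init(c(12, 5, 1), seed = 2)
  params$weights[[1]] <- params$weights[[1]] * unclass(mask)[, ]
  frozen <- net_config("quadratic", learning_rate = 0, iterations = 1)
  expect_identical(train_step(params, mask, X, y, frozen)$params$weights,
                   params$weights)
  for (i in 1:50) params <- train_step(params, mask, X, y, cfg)$params
  expect_true(all(params$weights[[1]][unclass(mask)[, ] == 0] == 0))
})

test_that("fit logs costs on schedule, is seed-deterministic, and descends", {
  sim <- generate_multiomics(20, 2, 60, 0.7, seed = 51)
  y <- generate_sf2(sim$truth, effect_size = 1.5, precision = 40, seed = 52)
  cfg <- net_config("quadratic", learning_rate = 0.05, iterations = 100,
                    seed = 6, log_every = 1)
  m1 <- fit_network(sim$X, y, c(20, 4, 1), config = cfg)
  m2 <- fit_network(sim$X, y, c(20, 4, 1), config = cfg)
  expect_equal(nrow(m1$history), 100L)
  expect_identical(m1$history, m2$history)
  drops <- diff(m1$history$cost) <= 1e-12
  expect_gte(mean(drops), 0.95)
})

test_that("survival fits rescale times and orient predictions by loss", {
  sim <- generate_multiomics(20, 2, 80, 0.7, seed = 61)
  sv <- generate_survival(sim$truth, effect_size = 1, censoring_rate = 0.2, seed = 62)
  sv_days <- survival_data(sv$time * 365, sv$event)
  cfg <- net_config("pqc", learning_rate = 0.1, iterations = 200, seed = 3)
  m <- fit_network(sim$X, sv_days, c(20, 4, 1), config = cfg)
  expect_equal(m$time_scale, max(sv_days$time))
  expect_identical(m$prediction_type, "time")
  expect_true(all(predict(m, sim$X) > 0))
  cfgn <- net_config("nlpl", learning_rate = 1e-4, iterations = 50, seed = 3)
  mn <- fit_network(sim$X, sv_days, c(20, 4, 1), config = cfgn)
  expect_identical(mn$prediction_type, "risk")
})

test_that("config validation enforces the loss/output pairing", {
  expect_error(net_config("quadratic", output_activation = "exp"), "sigmoid")
  expect_error(net_config("pqc", output_activation = "sigmoid"), "exp")
  expect_identical(net_config("nlpl")$output_activation, "exp")
  expect_identical(net_config("quadratic")$output_activation, "sigmoid")
})

test_that("PQC needs structurally fewer operations per iteration than NLPL", {
  set.seed(71)
  s <- survival_data(rexp(150) + 0.01, rbinom(150, 1, 0.7))
  ops <- survival_cost_op_counts(s)
  expect_lt(ops$pqc, ops$nlpl)
  # the gap widens with the event count
  s2 <- survival_data(s$time, rep(1, 150))
  expect_gt(survival_cost_op_counts(s2)$nlpl, ops$nlpl)
  expect_equal(survival_cost_op_counts(s2)$pqc, ops$pqc)
})

test_that("model archives round-trip predictions bit-exactly", {
  sim <- generate_multiomics(15, 3, 40, 0.7, seed = 81)
  y <- generate_sf2(sim$truth, seed = 82)
  mask <- suppressWarnings(build_scm(sim$X, 4, sparsity = 0.5, seed = 1))
  cfg <- net_config("quadratic", learning_rate = 0.1, iterations = 150, seed = 9)
  m <- fit_network(sim$X, y, c(15, 4, 1), mask = mask, config = cfg)
  dir <- tempfile()
  save_model(m, dir)
  back <- load_model(dir)
  expect_identical(predict(back, sim$X), predict(m, sim$X))
  expect_identical(back$layer_sizes, m$layer_sizes)
  expect_equal(unname(unclass(back$mask)[, ]), unname(unclass(m$mask)[, ]))
})
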