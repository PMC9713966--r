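fit_small_sf2 <- function(seed = 101, n_genes = 20, n = 80) {
  sim <- generate_multiomics(n_genes, 2, n, 0.7, seed = seed)
  y <- generate_sf2(sim$truth, effect_size = 1.5, precision = 40, seed = seed + 1)
  mask <- suppressWarnings(build_scm(sim$X, 4, sparsity = 0.5, seed = seed))
  cfg <- net_config("quadratic", learning_rate = 0.1, iterations = 300, seed = seed)
  model <- fit_network(sim$X, y, c(n_genes, 4, 1), mask = mask, config = cfg)
  list(sim = sim, y = y, mask = mask, model = model, cfg = cfg)
}

test_that("occlusion scores follow their defining arithmetic and leave the model intact", {
  f <- fit_small_sf2()
  snapshot <- f$model$params
  occ <- occlusion_test(f$model, f$sim$X, f$y)
  expect_identical(f$model$params, snapshot)
  expect_equal(nrow(occ), 20L)
  baseline <- attr(occ, "baseline")
  # recompute one gene by hand: zero its first-layer row, re-evaluate
  occluded <- f$model
  occluded$params$weights[[1]][7, ] <- 0
  manual <- rmse(predict(occluded, f$sim$X), f$y) - baseline
  expect_equal(occ$score[7], manual)
  # deterministic on reruns
  expect_identical(occ$score, occlusion_test(f$model, f$sim$X, f$y)$score)
})

test_that("a gene with an all-zero mask row scores exactly zero", {
  f <- fit_small_sf2()
  mask <- unclass(f$mask)[, ]
  mask[5, ] <- 0
  model <- fit_network(f$sim$X, f$y, c(20, 4, 1), mask = sc_mask(mask), config = f$cfg)
  occ <- occlusion_test(model, f$sim$X, f$y)
  expect_identical(occ$score[5], 0)
})

test_that("occlusion on survival models uses the concordance orientation", {
  sim <- generate_multiomics(20, 2, 80, 0.7, seed = 111)
  sv <- generate_survival(sim$truth, effect_size = 1, censoring_rate = 0.2, seed = 112)
  cfg <- net_config("pqc", learning_rate = 0.1, iterations = 300, seed = 5)
  model <- fit_network(sim$X, sv, c(20, 4, 1), config = cfg)
  occ <- occlusion_test(model, sim$X, sv)
  expect_equal(attr(occ, "metric"), "c_index")
  expect_equal(nrow(occ), 20L)
  expect_error(occlusion_test(model, sim$X, runif(80)), "task")
})

test_that("ensemble uncertainty is the across-member standard deviation", {
  f <- fit_small_sf2()
  ens <- ensemble_uncertainty(f$sim$X, f$y, c(20, 4, 1), mask = f$mask,
                              config = f$cfg, M = 3)
  preds <- attr(ens, "predictions")
  expect_equal(dim(preds), c(80L, 3L))
  expect_equal(ens$mean, rowMeans(preds))
  expect_equal(ens$uncertainty, apply(preds, 1, sd))
  # deviations around the member mean sum to zero per sample
  expect_equal(max(abs(rowSums(preds - ens$mean))), 0, tolerance = 1e-12)
  # identical seeds give identical members, hence zero uncertainty
  same <- ensemble_uncertainty(f$sim$X, f$y, c(20, 4, 1), mask = f$mask,
                               config = f$cfg, M = 3, seeds = c(7, 7, 7))
  expect_true(all(same$uncertainty == 0))
  expect_error(ensemble_uncertainty(f$sim$X, f$y, c(20, 4, 1), M = 1), "M >= 2")
})

test_that("single-gene-per-node masks reproduce their own gene's pattern best", {
  set.seed(121)
  n <- 60
  X <- matrix(runif(3 * n), 3, n,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:n)))
  mask <- sc_mask(diag(3))
  params <- xavier_init(c(3, 3, 1), seed = 2)
  # small weights keep SELU in its near-linear regime
  params$weights[[1]] <- diag(3) * 0.1
  model <- structure(list(params = params, mask = mask,
                          config = net_config("quadratic"),
                          layer_sizes = c(3L, 3L, 1L),
                          time_scale = NA_real_, task = "sf2",
                          prediction_type = "sf2", feature_ids = rownames(X)),
                     class = "gated_net")
  pr <- pattern_reproduction(model, X, grouping = 1:3)
  expect_equal(nrow(pr), 6L)  # 3 groups x 2 controls
  expect_true(all(pr$difference > 0))
  expect_true(all(pr$same_r > 0.99))
  expect_error(pattern_reproduction(model, X, grouping = rep(1, 3)), "2 groups")
})

test_that("node grouping covers all first-layer nodes", {
  set.seed(122)
  mask <- sc_mask(matrix(rbinom(60, 1, 0.5), 10, 6))
  g <- group_nodes(mask, 3)
  expect_equal(length(g), 6L)
  expect_equal(sort(unique(g)), 1:3)
  expect_error(group_nodes(mask, 1), "n_groups")
})

test_that("pairwise kappa matches hand computations", {
  m <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0), c = c(1, 1, 0, 0))
  k <- pairwise_kappa(m)
  # identical rows agree perfectly
  expect_equal(k["a", "c"], 1)
  # hand case: observed agreement 0.5, chance 0.5
  expect_equal(k["a", "b"], 0)
  expect_identical(k, t(k))
  # invariant to a common column permutation
  perm <- c(3, 1, 4, 2)
  expect_equal(pairwise_kappa(m[, perm]), k)
})

test_that("independent random connection profiles have near-zero mean kappa", {
  set.seed(123)
  m <- matrix(rbinom(2000 * 20, 1, 0.5), 2000, 20)
  k <- pairwise_kappa(m[1:1000 * 2 - 1, ])  # 1,000 disjoint-ish rows
  vals <- k[upper.tri(k)]
  expect_lt(abs(mean(vals, na.rm = TRUE)), 0.01)
})

test_that("mask kappa splits linked from unlinked pairs on a constructed mask", {
  # two blocks of genes with identical within-block profiles
  m <- rbind(matrix(rep(c(1, 1, 0, 0), 5), 5, 4, byrow = TRUE),
             matrix(rep(c(0, 0, 1, 1), 5), 5, 4, byrow = TRUE))
  rownames(m) <- paste0("g", 1:10)
  adj <- matrix(0L, 10, 10, dimnames = list(rownames(m), rownames(m)))
  adj[1:5, 1:5] <- 1L; adj[6:10, 6:10] <- 1L; diag(adj) <- 0L
  ks <- mask_kappa(sc_mask(m), adj)
  expect_equal(ks$mean_linked, 1)
  expect_equal(ks$mean_unlinked, -1)
  expect_lt(ks$p_value, 0.01)
  bad <- adj[1:9, 1:9]
  expect_error(mask_kappa(sc_mask(m), bad), "gene sets")
})
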