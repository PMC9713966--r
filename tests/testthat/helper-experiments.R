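# Shared synthetic experiments, cached so several tests can reuse one
# expensive run. Settings mirror the package's documented study
# conditions: 60 genes, 3 modules (module 1 informative), n = 200,
# within-module correlation 0.7, beta precision 40, SF2 effect 2.

.expt_cache <- new.env(parent = emptyenv())

sf2_experiment <- function(seed) {
  key <- paste0("sf2_", seed)
  if (!is.null(.expt_cache[[key]])) return(.expt_cache[[key]])
  sim <- generate_multiomics(60, 3, 200, 0.7, seed = seed)
  y <- generate_sf2(sim$truth, effect_size = 2, precision = 40, seed = seed + 100)
  folds <- make_folds(200, "kfold", 5, seed = seed + 200)
  cfg <- net_config("quadratic", learning_rate = 0.2, iterations = 3000,
                    seed = seed + 300)
  report <- suppressWarnings(cross_validate(
    sim$X, y, c(60, 6, 1), folds, config = cfg,
    mask_builder = function(Xtr) build_scm(Xtr, 6, sparsity = 0.8, seed = seed)))
  baseline <- mean(vapply(seq_len(folds$k), function(f) {
    te <- folds$assignments == f
    sqrt(mean((y[te] - mean(y[!te]))^2))
  }, numeric(1)))
  mask <- suppressWarnings(build_scm(sim$X, 6, sparsity = 0.8, seed = seed))
  model <- fit_network(sim$X, y, c(60, 6, 1), mask = mask, config = cfg)
  occ <- occlusion_test(model, sim$X, y)
  out <- list(sim = sim, y = y, report = report, baseline = baseline,
              improvement = 1 - report$mean_test / baseline,
              occlusion = occ, informative = sim$truth$module == 1)
  .expt_cache[[key]] <- out
  out
}
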