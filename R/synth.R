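#' Generate a synthetic multi-omics matrix with planted gene modules
#'
#' Genes are split into contiguous modules; each module has one latent
#' standard-normal activity per sample and every gene in the module is
#' `sqrt(rho) * activity + sqrt(1 - rho) * noise`, so the within-module
#' gene correlation is `rho` and between-module correlation is 0 by
#' construction. The latent Gaussian values are squashed into `(0, 1)`
#' elementwise by the standard-normal CDF, yielding an expression-channel
#' [omics_matrix()]. The elementwise map preserves the planted module
#' structure exactly: genes outside the informative module stay
#' statistically independent of the target-driving activity, which is
#' what makes the generator usable as ground truth for importance
#' scores. (A per-sample rank transform, appropriate for real data with
#' large gene panels, would couple every gene to every other at this
#' panel size and silently turn null genes informative.)
#'
#' @param n_genes Number of genes.
#' @param n_modules Number of modules (`<= n_genes`).
#' @param n_samples Number of samples.
#' @param within_module_corr Within-module correlation `rho` in `[0, 1)`.
#' @param informative_modules Indices of the modules whose activities
#'   drive the targets generated by [generate_sf2()] /
#'   [generate_survival()].
#' @param seed RNG seed.
#' @return List with `X` (the [omics_matrix()]) and `truth`
#'   (`synth_truth`: per-gene `module`, `informative` flag per module,
#'   latent `activities` (modules x samples), `rho`, `seed`).
#' @export
generate_multiomics <- function(n_genes = 60L, n_modules = 3L,
                                n_samples = 200L, within_module_corr = 0.7,
                                informative_modules = 1L, seed = 1L) {
  if (n_modules > n_genes) stopf("generate_multiomics: more modules than genes")
  if (within_module_corr < 0 || within_module_corr >= 1)
    stopf("generate_multiomics: within_module_corr must be in [0, 1)")
  if (length(informative_modules) < 1L ||
      any(!informative_modules %in% seq_len(n_modules)))
    stopf("generate_multiomics: invalid informative_modules")
  module <- sort(rep_len(seq_len(n_modules), n_genes))
  rho <- within_module_corr
  out <- with_seed(seed, {
    Z <- matrix(stats::rnorm(n_modules * n_samples), n_modules, n_samples)
    raw <- sqrt(rho) * Z[module, , drop = FALSE] +
      sqrt(1 - rho) * matrix(stats::rnorm(n_genes * n_samples),
                             n_genes, n_samples)
    list(Z = Z, raw = raw)
  })
  vals <- stats::pnorm(out$raw)   # N(0,1) marginals -> U(0,1), no cross-gene coupling
  rownames(vals) <- sprintf("G%03d", seq_len(n_genes))
  colnames(vals) <- sprintf("S%03d", seq_len(n_samples))
  X <- omics_matrix(vals, rep("Exp", n_genes))
  rownames(X) <- paste0("Exp:", rownames(vals))
  truth <- structure(list(module = module,
                          informative = seq_len(n_modules) %in% informative_modules,
                          activities = out$Z, rho = rho, seed = seed),
                     class = "synth_truth")
  list(X = X, truth = truth)
}

informative_activity <- function(truth) {
  Z <- truth$activities[truth$informative, , drop = FALSE]
  a <- colSums(Z)
  if (stats::sd(a) > 0) as.numeric(scale(a)) else a
}

#' Generate beta-distributed SF2 targets from planted module activity
#'
#' The mean surviving fraction is `sigmoid(effect_size * a)` where `a`
#' is the standardized activity of the informative module(s); realized
#' SF2 values are drawn from a beta distribution with that mean and the
#' given precision (`shape1 = mu * precision`,
#' `shape2 = (1 - mu) * precision`). The beta family mirrors the
#' empirical distribution of measured surviving fractions. With
#' `precision = Inf` the noise degenerates and SF2 equals the mean
#' exactly.
#'
#' @param truth `synth_truth` from [generate_multiomics()].
#' @param effect_size Slope of the latent activity on the logit scale
#'   (0 = uninformative targets).
#' @param precision Beta precision (sum of shape parameters), a scalar
#'   or one value per sample; larger = less noise. Must be positive.
#' @param seed RNG seed.
#' @return Numeric SF2 vector strictly inside `(0, 1)`.
#' @export
generate_sf2 <- function(truth, effect_size = 2, precision = 40, seed = 1L) {
  if (any(precision <= 0)) stopf("generate_sf2: precision must be positive")
  a <- informative_activity(truth)
  mu <- stats::plogis(effect_size * a)
  if (all(is.infinite(precision))) return(mu)
  m <- length(mu)
  phi <- rep_len(precision, m)
  y <- with_seed(seed, stats::rbeta(m, mu * phi, (1 - mu) * phi))
  pmin(pmax(y, 1e-6), 1 - 1e-6)
}

#' Generate survival targets with exponential hazards and uniform censoring
#'
#' Event times are exponential with rate
#' `baseline_scale * exp(effect_size * a)` (proportional hazards in the
#' informative-module activity `a`, so higher activity = higher risk =
#' shorter survival). Independent uniform censoring times `C ~ U(0, u)`
#' are applied, with `u` calibrated by root-finding so the expected
#' censored fraction matches `censoring_rate`.
#'
#' @param truth `synth_truth` from [generate_multiomics()].
#' @param effect_size Log-hazard slope of the latent activity.
#' @param baseline_scale Baseline hazard rate (positive).
#' @param censoring_rate Target fraction censored, in `[0, 1)`.
#' @param seed RNG seed.
#' @return A [survival_data()] object; the latent risk score is attached
#'   as the `risk` attribute, the calibrated censoring bound as `u`.
#' @export
generate_survival <- function(truth, effect_size = 1, baseline_scale = 1,
                              censoring_rate = 0.3, seed = 1L) {
  if (baseline_scale <= 0) stopf("generate_survival: baseline_scale must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stopf("generate_survival: censoring_rate must be in [0, 1)")
  a <- informative_activity(truth)
  risk <- effect_size * a
  out <- with_seed(seed, {
    Tev <- stats::rexp(length(a), rate = baseline_scale * exp(risk))
    if (censoring_rate == 0) {
      list(time = Tev, event = rep(1, length(Tev)), u = Inf)
    } else {
      # P(censored | u) = E[min(T, u)] / u, decreasing in u from 1 to 0
      f <- function(u) mean(pmin(Tev, u)) / u - censoring_rate
      u <- stats::uniroot(f, lower = 1e-9, upper = max(Tev) * 1e4,
                          tol = 1e-10)$root
      C <- stats::runif(length(Tev), 0, u)
      list(time = pmin(Tev, C), event = as.numeric(Tev <= C), u = u)
    }
  })
  surv <- survival_data(out$time, out$event)
  attr(surv, "risk") <- risk
  attr(surv, "u") <- out$u
  surv
}

#' Write synthetic ground truth as TSV
#'
#' One row per gene: gene id, module assignment, informative flag.
#'
#' @param X The [omics_matrix()] from [generate_multiomics()].
#' @param truth The matching `synth_truth`.
#' @param path File path.
#' @export
write_ground_truth <- function(X, truth, path) {
  df <- data.frame(gene = rownames(X), module = truth$module,
                   informative = as.integer(truth$informative[truth$module]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
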