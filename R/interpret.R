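#' Occlusion test for per-gene importance
#'
#' For each input gene, zeroes its row of the effective first-layer
#' weights (weights times mask), re-evaluates the model, and scores the
#' gene by the drop in fit quality: `RMSE(occluded) - RMSE(baseline)`
#' for SF2 models, `C-index(baseline) - C-index(occluded)` for survival
#' models. The model is left untouched; a gene whose mask row is all
#' zeros scores exactly 0 because occlusion changes nothing.
#'
#' @param model A fitted [fit_network()] model.
#' @param X Input matrix matching the model's features.
#' @param targets SF2 vector or [survival_data()] matching the model's
#'   task.
#' @return `occlusion_result` data frame with columns `feature`, `score`
#'   and `rank` (1 = most important); the baseline metric is attached as
#'   the `baseline` attribute.
#' @export
occlusion_test <- function(model, X, targets) {
  X <- as_values(X)
  is_surv <- inherits(targets, "survival_data")
  if (is_surv != identical(model$task, "survival"))
    stopf("occlusion_test: target type does not match the model's task")
  eval_metric <- function(m) {
    if (is_surv) c_index(predicted_time_orientation(m, X), targets)
    else rmse(predict(m, X), targets)
  }
  baseline <- eval_metric(model)
  W1 <- model$params$weights[[1L]]
  n_genes <- nrow(W1)
  scores <- vapply(seq_len(n_genes), function(i) {
    occluded <- model
    occluded$params$weights[[1L]][i, ] <- 0
    occ <- eval_metric(occluded)
    if (is_surv) baseline - occ else occ - baseline
  }, numeric(1))
  features <- model$feature_ids %||% rownames(X) %||% paste0("g", seq_len(n_genes))
  out <- data.frame(feature = features, score = scores,
                    rank = rank(-scores, ties.method = "min"))
  attr(out, "baseline") <- baseline
  attr(out, "metric") <- if (is_surv) "c_index" else "rmse"
  class(out) <- c("occlusion_result", "data.frame")
  out
}

#' Deep-ensemble epistemic uncertainty
#'
#' Trains `M` models that differ only in their initialization seed, and
#' reports the per-sample mean prediction and the standard deviation of
#' the `M` outputs as the epistemic uncertainty: samples the ensemble
#' members disagree on are samples the model family is unsure about.
#'
#' @param X Input matrix (features x samples).
#' @param targets SF2 vector or [survival_data()].
#' @param layer_sizes,mask,config As in [fit_network()].
#' @param M Ensemble size (default 5).
#' @param seeds Optional `M` distinct initialization seeds; defaults to
#'   `config$seed + 0:(M-1)`.
#' @return `ensemble_result` data frame with `sample`, `mean`,
#'   `uncertainty`; the full `M`-column prediction matrix is attached as
#'   the `predictions` attribute, the fitted members as `models`.
#' @export
ensemble_uncertainty <- function(X, targets, layer_sizes, mask = NULL,
                                 config = net_config(), M = 5L, seeds = NULL) {
  X <- as_values(X)
  M <- as.integer(M)
  if (M < 2L) stopf("ensemble_uncertainty: need M >= 2")
  seeds <- seeds %||% (config$seed + seq_len(M) - 1L)
  if (length(seeds) != M)
    stopf("ensemble_uncertainty: need exactly M seeds")
  models <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- as.integer(s)
    fit_network(X, targets, layer_sizes, mask = mask, config = cfg)
  })
  preds <- vapply(models, function(m) predict(m, X), numeric(ncol(X)))
  out <- data.frame(sample = colnames(X) %||% seq_len(ncol(X)),
                    mean = rowMeans(preds),
                    uncertainty = apply(preds, 1L, stats::sd))
  attr(out, "predictions") <- preds
  attr(out, "models") <- models
  class(out) <- c("ensemble_result", "data.frame")
  out
}

#' Group first-layer nodes by their mask columns
#'
#' Agglomerative (complete-linkage) clustering of the mask columns into
#' `n_groups` groups of nodes with similar gene-connection profiles.
#'
#' @param mask An [sc_mask()].
#' @param n_groups Number of node groups.
#' @return Integer group label per node.
#' @export
group_nodes <- function(mask, n_groups) {
  K <- ncol(mask)
  if (n_groups < 2L || n_groups > K)
    stopf("group_nodes: n_groups must be in 2..%d", K)
  hc <- stats::hclust(stats::dist(t(as_values(mask))), method = "complete")
  stats::cutree(hc, k = n_groups)
}

#' Gene-pattern reproduction of the first hidden layer
#'
#' Checks that group-specific first-layer nodes reproduce the sample
#' similarity carried by their group-specific genes. For each node
#' group, the group-specific genes are those connected (mask = 1) in
#' more than half of the group's nodes. The node-based sample-similarity
#' matrix (Pearson correlation across samples of the group's first-layer
#' outputs) is correlated - over the upper triangle - with the
#' gene-based sample-similarity matrix of each group's specific genes.
#' Same-group agreement minus cross-group (control) agreement is the
#' reported statistic; positive differences mean the hidden nodes
#' learned their own genes' pattern rather than a generic one.
#'
#' @param model A fitted [fit_network()] model with a mask.
#' @param X Input matrix matching the model.
#' @param grouping Integer group label per first-layer node, e.g. from
#'   [group_nodes()]; at least 2 groups.
#' @return Data frame with one row per ordered (group, control) pair:
#'   `group`, `control`, `same_r`, `control_r`,
#'   `difference = same_r - control_r`.
#' @export
pattern_reproduction <- function(model, X, grouping) {
  if (is.null(model$mask)) stopf("pattern_reproduction: model has no mask")
  X <- as_values(X)
  mask <- model$mask
  groups <- sort(unique(grouping))
  if (length(grouping) != ncol(mask))
    stopf("pattern_reproduction: one group label per first-layer node required")
  if (length(groups) < 2L) stopf("pattern_reproduction: need at least 2 groups")
  fw <- net_forward(model$params, mask, X, model$config$output_activation)
  L1 <- fw$A[[2L]]                               # nodes x samples
  upper <- function(M) M[upper.tri(M)]
  node_sim <- list(); gene_sim <- list()
  for (g in groups) {
    nodes <- which(grouping == g)
    specific <- which(rowMeans(mask[, nodes, drop = FALSE]) > 0.5)
    if (length(specific) == 0L)
      stopf("pattern_reproduction: group %s has no group-specific gene", g)
    # sample-by-sample similarity: correlate the samples (columns) over
    # the group's node outputs / specific genes; with a single node or
    # gene, fall back to negative absolute difference
    if (length(nodes) == 1L) {
      v <- as.numeric(L1[nodes, ])
      ns <- -abs(outer(v, v, "-"))
    } else {
      ns <- suppressWarnings(stats::cor(L1[nodes, , drop = FALSE]))
    }
    if (length(specific) == 1L) {
      v <- as.numeric(X[specific, ])
      gs <- -abs(outer(v, v, "-"))
    } else {
      gs <- suppressWarnings(stats::cor(X[specific, , drop = FALSE]))
    }
    node_sim[[as.character(g)]] <- upper(ns)
    gene_sim[[as.character(g)]] <- upper(gs)
  }
  rows <- list()
  for (g in groups) {
    same_r <- stats::cor(node_sim[[as.character(g)]], gene_sim[[as.character(g)]])
    for (ctrl in setdiff(groups, g)) {
      control_r <- stats::cor(node_sim[[as.character(g)]],
                              gene_sim[[as.character(ctrl)]])
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, control = ctrl, same_r = same_r, control_r = control_r,
        difference = same_r - control_r)
    }
  }
  do.call(rbind, rows)
}

#' Pairwise Cohen's kappa between mask rows
#'
#' Treats each gene's connection profile (its binary mask row over the
#' K nodes) as a rating and computes the standard two-rater Cohen's
#' kappa for every gene pair: observed agreement corrected for the
#' agreement expected from the two rows' marginal on-rates. Pairs where
#' chance agreement is exactly 1 (both rows constant and identical in
#' expectation) are undefined and returned as `NA`.
#'
#' @param mask An [sc_mask()] or binary genes x nodes matrix.
#' @return Symmetric genes x genes matrix of kappa values (diagonal
#'   `NA`).
#' @export
pairwise_kappa <- function(mask) {
  M <- as_values(mask)
  K <- ncol(M)
  po <- (tcrossprod(M) + tcrossprod(1 - M)) / K
  p <- rowMeans(M)
  pe <- outer(p, p) + outer(1 - p, 1 - p)
  kap <- (po - pe) / (1 - pe)
  kap[pe >= 1 - 1e-12] <- NA_real_
  diag(kap) <- NA_real_
  dimnames(kap) <- list(rownames(M), rownames(M))
  kap
}

#' Validate a mask against a prior gene-interaction network
#'
#' Compares the connection-profile agreement (pairwise Cohen's kappa of
#' mask rows) between interacting and non-interacting gene pairs. If the
#' mask encodes the biology of the prior network, interlinked genes
#' should share connection profiles and show higher kappa.
#'
#' @param mask An [sc_mask()] with gene rownames matching `interactions`.
#' @param interactions Symmetric binary adjacency matrix (e.g. from
#'   [read_interactions()]) over the same genes.
#' @return `mask_kappa_summary` list: `mean_linked`, `mean_unlinked`,
#'   `n_linked`, `n_unlinked`, Wilcoxon rank-sum `statistic` and
#'   `p_value`, and the per-pair `kappa` matrix.
#' @export
mask_kappa <- function(mask, interactions) {
  M <- as_values(mask); A <- as.matrix(interactions)
  if (nrow(M) != nrow(A))
    stopf("mask_kappa: mask and interaction matrix cover different gene sets")
  if (!is.null(rownames(M)) && !is.null(rownames(A))) {
    if (!setequal(rownames(M), rownames(A)))
      stopf("mask_kappa: mask and interaction matrix cover different gene sets")
    A <- A[rownames(M), rownames(M)]
  }
  kap <- pairwise_kappa(M)
  ut <- upper.tri(kap)
  linked <- A[ut] == 1 & !is.na(kap[ut])
  unlinked <- A[ut] == 0 & !is.na(kap[ut])
  kl <- kap[ut][linked]; ku <- kap[ut][unlinked]
  if (length(kl) == 0L || length(ku) == 0L)
    stopf("mask_kappa: need both linked and unlinked gene pairs")
  wt <- stats::wilcox.test(kl, ku, alternative = "two.sided", exact = FALSE)
  structure(list(mean_linked = mean(kl), mean_unlinked = mean(ku),
                 n_linked = length(kl), n_unlinked = length(ku),
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 kappa = kap),
            class = "mask_kappa_summary")
}

#' @export
print.mask_kappa_summary <- function(x, ...) {
  cat(sprintf(paste0("mask_kappa: mean kappa %.3f over %d linked pairs vs ",
                     "%.3f over %d unlinked pairs (Wilcoxon p = %.3g)\n"),
              x$mean_linked, x$n_linked, x$mean_unlinked, x$n_unlinked,
              x$p_value))
  invisible(x)
}

#' Write occlusion scores as TSV
#' @param result An [occlusion_test()] result.
#' @param path File path.
#' @export
write_occlusion <- function(result, path) {
  utils::write.table(as.data.frame(result)[order(result$rank), ], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
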