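#' Save a fitted gated network as a plain-text archive
#'
#' Writes one directory holding a YAML manifest (layer sizes, training
#' configuration, time scale, task), one TSV per weight matrix and bias
#' vector, the mask, and the training history. Numbers are written with
#' 17 significant digits so [load_model()] reproduces predictions
#' bit-exactly.
#'
#' @param model A [fit_network()] model.
#' @param dir Directory to create (must not already contain a manifest).
#' @return The directory path, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  L <- length(model$params$weights)
  manifest <- list(
    package = "genegate", object = "gated_net",
    layer_sizes = as.integer(model$layer_sizes),
    loss = model$config$loss,
    output_activation = model$config$output_activation,
    learning_rate = model$config$learning_rate,
    iterations = model$config$iterations,
    seed = model$config$seed,
    log_every = model$config$log_every,
    diag_every = model$config$diag_every,
    time_scale = if (is.na(model$time_scale)) "NA"
                 else sprintf("%.17g", model$time_scale),
    task = model$task,
    prediction_type = model$prediction_type,
    has_mask = !is.null(model$mask),
    n_layers = L)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  for (l in seq_len(L)) {
    W <- model$params$weights[[l]]
    rownames(W) <- rownames(W) %||% paste0("r", seq_len(nrow(W)))
    colnames(W) <- colnames(W) %||% paste0("c", seq_len(ncol(W)))
    write_gene_matrix(W, file.path(dir, sprintf("weights_%d.tsv", l)))
    b <- model$params$biases[[l]]
    utils::write.table(
      data.frame(index = seq_along(b), value = sprintf("%.17g", b)),
      file.path(dir, sprintf("biases_%d.tsv", l)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(model$mask)) {
    mask <- model$mask
    rownames(mask) <- model$feature_ids %||% rownames(mask) %||%
      paste0("g", seq_len(nrow(mask)))
    write_mask(mask, file.path(dir, "mask.tsv"))
  }
  utils::write.table(model$history, file.path(dir, "history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(model$diag))
    utils::write.table(model$diag, file.path(dir, "diag.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(model$feature_ids))
    writeLines(model$feature_ids, file.path(dir, "features.txt"))
  invisible(dir)
}

#' Load a gated network saved by [save_model()]
#'
#' @param dir Archive directory.
#' @return A `gated_net` model whose predictions match the saved model
#'   bit-exactly.
#' @export
load_model <- function(dir) {
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) stopf("load_model: no manifest in %s", dir)
  man <- yaml::read_yaml(mf)
  L <- man$n_layers
  weights <- vector("list", L); biases <- vector("list", L)
  for (l in seq_len(L)) {
    W <- read_gene_matrix(file.path(dir, sprintf("weights_%d.tsv", l)))
    dimnames(W) <- NULL
    weights[[l]] <- W
    bt <- utils::read.table(file.path(dir, sprintf("biases_%d.tsv", l)),
                            header = TRUE, sep = "\t")
    biases[[l]] <- as.numeric(bt$value)
  }
  mask <- NULL
  if (isTRUE(man$has_mask)) {
    mask <- read_mask(file.path(dir, "mask.tsv"))
  }
  config <- net_config(loss = man$loss,
                       output_activation = man$output_activation,
                       learning_rate = man$learning_rate,
                       iterations = man$iterations, seed = man$seed,
                       log_every = man$log_every, diag_every = man$diag_every)
  history <- utils::read.table(file.path(dir, "history.tsv"),
                               header = TRUE, sep = "\t")
  diag_path <- file.path(dir, "diag.tsv")
  diag <- if (file.exists(diag_path))
    utils::read.table(diag_path, header = TRUE, sep = "\t") else NULL
  feat_path <- file.path(dir, "features.txt")
  feature_ids <- if (file.exists(feat_path)) readLines(feat_path) else NULL
  params <- structure(list(weights = weights, biases = biases,
                           layer_sizes = as.integer(man$layer_sizes)),
                      class = "network_params")
  structure(list(params = params, mask = mask, config = config,
                 layer_sizes = as.integer(man$layer_sizes),
                 history = history, diag = diag,
                 time_scale = if (identical(man$time_scale, "NA")) NA_real_
                              else as.numeric(man$time_scale),
                 task = man$task, prediction_type = man$prediction_type,
                 feature_ids = feature_ids),
            class = "gated_net")
}
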