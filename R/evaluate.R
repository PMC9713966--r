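#' Survival data container
#'
#' Follow-up times and event flags. The risk set at a time `t` is
#' everyone still under observation then, i.e. `{j : T_j >= t}`.
#'
#' @param time Positive follow-up or event times.
#' @param event Event flags: 1 = event observed, 0 = censored.
#' @return `survival_data` list with `time` and `event`.
#' @export
survival_data <- function(time, event) {
  time <- as.numeric(time); event <- as.numeric(event)
  if (length(time) != length(event)) stopf("survival_data: length mismatch")
  if (any(!is.finite(time)) || any(time <= 0))
    stopf("survival_data: times must be positive and finite")
  if (!all(event %in% c(0, 1))) stopf("survival_data: event flags must be 0 or 1")
  structure(list(time = time, event = event), class = "survival_data")
}

as_survival <- function(x) {
  if (inherits(x, "survival_data")) return(x)
  if (is.list(x) && all(c("time", "event") %in% names(x)))
    return(survival_data(x$time, x$event))
  stopf("expected a survival_data object")
}

#' @export
`[.survival_data` <- function(x, i) survival_data(x$time[i], x$event[i])

#' @export
length.survival_data <- function(x) length(x$time)

#' @export
print.survival_data <- function(x, ...) {
  cat(sprintf("survival_data: %d samples, %d events (%.1f%% censored)\n",
              length(x$time), sum(x$event),
              100 * mean(x$event == 0)))
  invisible(x)
}

#' Root mean squared error
#'
#' @param pred,truth Equal-length numeric vectors.
#' @return `sqrt(mean((pred - truth)^2))`.
#' @export
rmse <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0L)
    stopf("rmse: need equal non-empty lengths")
  sqrt(mean((pred - truth)^2))
}

#' Harrell's concordance index
#'
#' Proportion of concordant pairs among comparable pairs. A pair `(i, j)`
#' with `T_i < T_j` is comparable iff sample `i` had the event (ties in
#' time are not comparable). With predictions on the predicted-time
#' orientation (larger = longer survival) the pair is concordant when
#' `pred_i < pred_j`; tied predictions earn 0.5 credit.
#'
#' @param pred Predicted survival times or any monotone score on the
#'   same orientation.
#' @param surv A [survival_data()] object, or a time vector when `event`
#'   is supplied.
#' @param event Optional event flags when `surv` is a plain time vector.
#' @return Concordance in `[0, 1]`; `NA` with a warning when no pair is
#'   comparable.
#' @export
c_index <- function(pred, surv, event = NULL) {
  if (!is.null(event)) surv <- survival_data(surv, event)
  surv <- as_survival(surv)
  T <- surv$time; E <- surv$event
  if (length(pred) != length(T)) stopf("c_index: length mismatch")
  comp <- outer(T, T, "<") & (E == 1)          # comp[i, j]: comparable pair
  den <- sum(comp)
  if (den == 0L) {
    warnf("c_index: no comparable pairs; returning NA")
    return(NA_real_)
  }
  conc <- outer(pred, pred, "<")
  tie <- outer(pred, pred, "==")
  (sum(comp & conc) + 0.5 * sum(comp & tie)) / den
}

#' Cross-validation fold assignment
#'
#' Samples are shuffled once under the seed and cut into contiguous
#' blocks; the first `n %% k` folds get one extra sample. Leave-one-out
#' is k-fold with `k = n`.
#'
#' @param n Number of samples.
#' @param scheme `"kfold"` or `"loo"`.
#' @param k Number of folds for `"kfold"`.
#' @param seed RNG seed for the shuffle.
#' @return `fold_split` list with `scheme`, `k`, `assignments` (fold
#'   index per sample), `seed`.
#' @export
make_folds <- function(n, scheme = c("kfold", "loo"), k = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "loo") k <- n
  k <- as.integer(k)
  if (k > n) stopf("make_folds: k = %d exceeds n = %d", k, n)
  if (k < 2L) stopf("make_folds: need at least 2 folds")
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  perm <- with_seed(seed, sample.int(n))
  assignments <- integer(n)
  assignments[perm] <- rep(seq_len(k), times = sizes)
  structure(list(scheme = scheme, k = k, assignments = assignments, seed = seed),
            class = "fold_split")
}

#' Cross-validated fit of a gated network
#'
#' For each fold the mask is rebuilt on the training samples only (no
#' information leaks from the held-out fold into the mask), the network
#' is fitted, and the task metric is reported on the training and test
#' portions: RMSE for SF2, C-index for survival (NLPL risk scores are
#' re-oriented internally).
#'
#' @param X Input matrix (features x samples) or [omics_matrix()].
#' @param targets SF2 vector or [survival_data()].
#' @param layer_sizes Full layer sizes as in [fit_network()].
#' @param folds A [make_folds()] split.
#' @param config A [net_config()].
#' @param mask_builder `NULL` for full connection, or a function
#'   `function(X_train) -> sc_mask` called once per fold.
#' @return `metric_report` list: `folds` data frame (fold, train, test),
#'   `mean_train`, `mean_test`, `metric` name.
#' @export
cross_validate <- function(X, targets, layer_sizes, folds,
                           config = net_config(), mask_builder = NULL) {
  X <- as_values(X)
  is_surv <- inherits(targets, "survival_data")
  metric <- if (is_surv) "c_index" else "rmse"
  res <- lapply(seq_len(folds$k), function(f) {
    tr <- folds$assignments != f
    te <- !tr
    out <- tryCatch({
      Xtr <- X[, tr, drop = FALSE]; Xte <- X[, te, drop = FALSE]
      ttr <- if (is_surv) targets[tr] else targets[tr]
      tte <- if (is_surv) targets[te] else targets[te]
      mask <- if (is.null(mask_builder)) NULL else mask_builder(Xtr)
      model <- fit_network(Xtr, ttr, layer_sizes, mask = mask, config = config)
      if (is_surv) {
        c(train = c_index(predicted_time_orientation(model, Xtr), ttr),
          test = c_index(predicted_time_orientation(model, Xte), tte))
      } else {
        c(train = rmse(predict(model, Xtr), ttr),
          test = rmse(predict(model, Xte), tte))
      }
    }, error = function(e)
      stopf("cross_validate: fold %d failed: %s", f, conditionMessage(e)))
    out
  })
  df <- data.frame(fold = seq_len(folds$k),
                   train = vapply(res, `[[`, numeric(1), "train"),
                   test = vapply(res, `[[`, numeric(1), "test"))
  structure(list(folds = df, mean_train = mean(df$train),
                 mean_test = mean(df$test), metric = metric),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report (%s): mean train %.4f, mean test %.4f over %d folds\n",
              x$metric, x$mean_train, x$mean_test, nrow(x$folds)))
  invisible(x)
}

#' Write a metric report as TSV
#'
#' Layout mirrors the conventional cross-validation table: one row per
#' split (training/testing), columns Mean, CV1..CVk.
#'
#' @param report A [cross_validate()] result.
#' @param path File path.
#' @export
write_metric_report <- function(report, path) {
  k <- nrow(report$folds)
  tab <- rbind(Training = c(report$mean_train, report$folds$train),
               Testing = c(report$mean_test, report$folds$test))
  colnames(tab) <- c("Mean", paste0("CV", seq_len(k)))
  df <- data.frame(split = rownames(tab),
                   matrix(sprintf("%.6f", tab), nrow = 2L,
                          dimnames = list(NULL, colnames(tab))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
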