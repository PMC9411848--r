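# Grid-searched pipelines over the 281-column feature tables. Each pipeline
# is scaler -> variance threshold -> classifier, with the scaler and the
# threshold fitted on training folds only. Grids follow the published
# hyperparameter ranges; the closed-form configuration counts (48 KNN,
# 625 SVM, 48 DT, 9 NB) are asserted in tests.

TABLE_SCALERS <- c("normalizer", "minmax", "standard", "maxabs")
VARIANCE_THRESHOLDS <- c(0, 0.001, 0.005, 0.01, 0.05, 0.1, 0.5)

#' Enumerate a classifier's hyperparameter grid
#'
#' KNN: nNeighbors \{1,2,3,5,7,10\} x leafSize \{1,5,10,15\} x p \{1,2\};
#' SVM: degree 1..5 x C \{0.1,1,10,100,1000\} x gamma \{1,...,1e-4\} x
#' kernel \{linear,poly,rbf,sigmoid,precomputed\}; DT: criterion x splitter x
#' maxDepth 3..14; NB: alpha \{0,0.1,0.5,1,1.5,2,3,5,10\}.
#'
#' @param classifier_kind one of `"KNN"`, `"SVM"`, `"DT"`, `"NB"`.
#' @return list of named parameter lists (classifier part only).
#' @export
build_grid <- function(classifier_kind) {
  assert_that(classifier_kind %in% CLASSIFIER_KINDS,
              "unknown classifier '%s'; valid: %s", classifier_kind,
              paste(CLASSIFIER_KINDS, collapse = ", "))
  grid_df <- switch(classifier_kind,
    KNN = expand.grid(nNeighbors = c(1, 2, 3, 5, 7, 10),
                      leafSize = c(1, 5, 10, 15),
                      p = c(1, 2), stringsAsFactors = FALSE),
    SVM = expand.grid(degree = 1:5,
                      C = c(0.1, 1, 10, 100, 1000),
                      gamma = c(1, 0.1, 0.01, 0.001, 0.0001),
                      kernel = c("linear", "poly", "rbf", "sigmoid", "precomputed"),
                      stringsAsFactors = FALSE),
    DT = expand.grid(criterion = c("gini", "entropy"),
                     splitter = c("best", "random"),
                     maxDepth = 3:14, stringsAsFactors = FALSE),
    NB = expand.grid(alpha = c(0, 0.1, 0.5, 1.0, 1.5, 2, 3, 5, 10),
                     stringsAsFactors = FALSE))
  lapply(seq_len(nrow(grid_df)), function(i) as.list(grid_df[i, , drop = FALSE]))
}

#' A full pipeline configuration
#' @param scaler one of `"normalizer"`, `"minmax"`, `"standard"`, `"maxabs"`.
#' @param variance_threshold variance cutoff for the feature filter.
#' @param classifier_kind classifier tag.
#' @param classifier_params named list from [build_grid()].
#' @export
grid_config <- function(scaler, variance_threshold, classifier_kind,
                        classifier_params = list()) {
  assert_that(scaler %in% TABLE_SCALERS, "unknown table scaler '%s'", scaler)
  structure(list(scaler = scaler, variance_threshold = variance_threshold,
                 classifier_kind = classifier_kind,
                 classifier_params = classifier_params),
            class = "grid_config")
}

# Table scalers: fit on training rows, apply to any rows. "normalizer" is the
# stateless per-row unit-norm scaling; the others are per-column.
fit_table_scaler <- function(x, scaler) {
  switch(scaler,
    normalizer = list(kind = "normalizer"),
    minmax = list(kind = "minmax", lo = apply(x, 2, min), hi = apply(x, 2, max)),
    standard = list(kind = "standard", mu = colMeans(x), sd = apply(x, 2, stats::sd)),
    maxabs = list(kind = "maxabs", m = apply(abs(x), 2, max)))
}

apply_table_scaler <- function(fit, x) {
  switch(fit$kind,
    normalizer = x / pmax(sqrt(rowSums(x^2)), EPS_FLOOR),
    minmax = sweep(sweep(x, 2, fit$lo), 2, pmax(fit$hi - fit$lo, EPS_FLOOR), "/"),
    standard = sweep(sweep(x, 2, fit$mu), 2, pmax(fit$sd, EPS_FLOOR), "/"),
    maxabs = sweep(x, 2, pmax(fit$m, EPS_FLOOR), "/"))
}

#' Fit a full pipeline on a feature table
#'
#' @param config a [grid_config()].
#' @param table a `feature_table` (or list with `x`, `y`).
#' @param seed optional seed (DT random splitter).
#' @return a `pd_pipeline` with `predict` support.
#' @export
fit_pipeline <- function(config, table, seed = NULL) {
  dat <- if (inherits(table, "feature_table")) feature_matrix(table) else table
  scaler_fit <- fit_table_scaler(dat$x, config$scaler)
  xs <- apply_table_scaler(scaler_fit, dat$x)
  vars <- apply(xs, 2, stats::var)
  keep <- which(vars > config$variance_threshold)
  if (!length(keep)) abort_validation("no features survive variance threshold %g",
                                      config$variance_threshold)
  clf <- fit_classifier(config$classifier_kind, xs[, keep, drop = FALSE], dat$y,
                        config$classifier_params, seed = seed)
  structure(list(config = config, scaler_fit = scaler_fit, keep = keep,
                 classifier = clf, classes = clf$classes),
            class = "pd_pipeline")
}

#' @export
predict.pd_pipeline <- function(object, newx, ...) {
  if (inherits(newx, "feature_table")) newx <- feature_matrix(newx)$x
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1)
  xs <- apply_table_scaler(object$scaler_fit, newx)
  predict(object$classifier, xs[, object$keep, drop = FALSE])
}

# Stratified fold assignment: within-class shuffle, then round-robin.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated evaluation of one pipeline configuration
#'
#' Stratified k-fold CV; scaler and variance threshold fitted on the training
#' folds only; metrics averaged across folds.
#'
#' @param config a [grid_config()].
#' @param table a `feature_table`.
#' @param k_folds number of folds (default 10).
#' @param seed optional seed controlling fold assignment.
#' @return `metrics_report` with `per_fold` data frame and pooled confusion
#'   counts attached.
#' @export
evaluate_config <- function(config, table, k_folds = 10, seed = NULL) {
  dat <- if (inherits(table, "feature_table")) feature_matrix(table) else table
  counts <- table(dat$y)
  assert_that(all(counts >= k_folds),
              "need at least k_folds = %d rows per class (have min %d)",
              k_folds, min(counts))
  classes <- sort(unique(dat$y))
  with_seed_or_stream(seed, {
    fold <- stratified_folds(dat$y, k_folds)
    per_fold <- vector("list", k_folds)
    cm_total <- NULL
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      pipe <- fit_pipeline(config, list(x = dat$x[tr, , drop = FALSE], y = dat$y[tr]))
      probs <- predict(pipe, dat$x[!tr, , drop = FALSE])
      # align columns to the global class set
      full <- matrix(0, nrow(probs), length(classes), dimnames = list(NULL, classes))
      full[, colnames(probs)] <- probs
      m <- ml_metrics(dat$y[!tr], full, classes)
      per_fold[[f]] <- data.frame(fold = f, accuracy = m$accuracy,
                                  precision = m$precision, recall = m$recall,
                                  f1 = m$f1, auc = m$auc)
      cm_total <- if (is.null(cm_total)) m$confusion else cm_total + m$confusion
    }
    pf <- do.call(rbind, per_fold)
    structure(list(accuracy = mean(pf$accuracy), precision = mean(pf$precision),
                   recall = mean(pf$recall), f1 = mean(pf$f1),
                   auc = mean(pf$auc), confusion = cm_total, per_fold = pf),
              class = "metrics_report")
  })
}

#' Grid search over a classifier's full pipeline space
#'
#' Evaluates the classifier grid crossed with the four table scalers and the
#' seven variance thresholds. Best = highest mean CV accuracy, ties broken by
#' enumeration order. Configurations that fail (e.g. the `precomputed`
#' kernel, which has no kernel matrix defined) are logged and scored invalid
#' rather than aborting the search.
#'
#' @param classifier_kind classifier tag.
#' @param table a `feature_table`.
#' @param k_folds folds for [evaluate_config()].
#' @param seed seed controlling fold assignment (shared by all configs).
#' @param scalers,thresholds optional subsets to shrink the search space
#'   (defaults: all four scalers, all seven thresholds).
#' @param classifier_grid optional reduced classifier grid (default:
#'   [build_grid()] output).
#' @return list with `best_config`, `best_metrics`, `results` (one row per
#'   configuration).
#' @export
grid_search <- function(classifier_kind, table, k_folds = 10, seed = NULL,
                        scalers = TABLE_SCALERS,
                        thresholds = VARIANCE_THRESHOLDS,
                        classifier_grid = build_grid(classifier_kind)) {
  rows <- list()
  best <- NULL
  i <- 0L
  for (params in classifier_grid) {
    for (scaler in scalers) {
      for (thr in thresholds) {
        i <- i + 1L
        config <- grid_config(scaler, thr, classifier_kind, params)
        metrics <- tryCatch(
          evaluate_config(config, table, k_folds = k_folds, seed = seed),
          error = function(e) {
            warning(sprintf("config %d invalid (%s); skipped", i, conditionMessage(e)))
            NULL
          })
        rows[[i]] <- data.frame(
          config_id = i, scaler = scaler, variance_threshold = thr,
          params = paste(names(params), unlist(params), sep = "=", collapse = ";"),
          accuracy = metrics$accuracy %||% NA_real_,
          precision = metrics$precision %||% NA_real_,
          recall = metrics$recall %||% NA_real_,
          f1 = metrics$f1 %||% NA_real_, auc = metrics$auc %||% NA_real_)
        if (!is.null(metrics) &&
            (is.null(best) || metrics$accuracy > best$metrics$accuracy)) {
          best <- list(config = config, metrics = metrics, config_id = i)
        }
      }
    }
  }
  assert_that(!is.null(best), "every configuration failed")
  list(best_config = best$config, best_metrics = best$metrics,
       results = do.call(rbind, rows))
}
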