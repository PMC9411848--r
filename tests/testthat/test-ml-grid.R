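# Grid enumeration, pipeline evaluation and grid search.

test_that("classifier grids match the closed-form configuration counts", {
  expect_length(build_grid("KNN"), 48)   # 6 x 4 x 2
  expect_length(build_grid("SVM"), 625)  # 5 x 5 x 5 x 5
  expect_length(build_grid("DT"), 48)    # 2 x 2 x 12
  expect_length(build_grid("NB"), 9)
  expect_error(build_grid("RF"), "unknown classifier")
  # full search space per classifier = grid x 4 scalers x 7 thresholds
  expect_equal(length(build_grid("KNN")) * 4 * 7, 1344)
})

test_that("a separable table scores perfect accuracy for every classifier", {
  tbl <- make_separable_table(n_per_class = 20, shift = 6)
  configs <- list(
    grid_config("minmax", 0, "KNN", list(nNeighbors = 3, leafSize = 1, p = 2)),
    grid_config("standard", 0, "DT", list(criterion = "gini", splitter = "best",
                                          maxDepth = 5)),
    grid_config("maxabs", 0, "NB", list(alpha = 0.1)),
    grid_config("minmax", 0, "SVM", list(C = 10, kernel = "rbf", gamma = 0.5,
                                         degree = 3)))
  for (cfg in configs) {
    m <- evaluate_config(cfg, tbl, k_folds = 5, seed = 1)
    expect_equal(m$accuracy, 1.0, label = cfg$classifier_kind)
  }
})

test_that("micro-averaged precision, recall and F1 equal accuracy", {
  tbl <- make_separable_table(n_per_class = 15, shift = 1.5)  # imperfect
  cfg <- grid_config("standard", 0, "NB", list(alpha = 1))
  m <- evaluate_config(cfg, tbl, k_folds = 5, seed = 2)
  expect_equal(m$precision, m$accuracy)
  expect_equal(m$recall, m$accuracy)
  expect_equal(m$f1, m$accuracy)
  expect_true(m$auc >= 0 && m$auc <= 1)
  expect_equal(sum(m$confusion), 30)
})

test_that("shuffled labels give chance-level accuracy and AUC near 0.5", {
  withr::with_seed(3, {
    tbl <- make_separable_table(n_per_class = 40, shift = 0)  # null data
    cfg <- grid_config("standard", 0, "KNN", list(nNeighbors = 7, p = 2))
    m <- evaluate_config(cfg, tbl, k_folds = 5, seed = 4)
    expect_lt(abs(m$accuracy - 0.5), 0.2)
    expect_lt(abs(m$auc - 0.5), 0.2)
  })
})

test_that("an impossible variance threshold is a validation error", {
  tbl <- make_separable_table()
  cfg <- grid_config("minmax", 1e6, "KNN", list(nNeighbors = 1, p = 2))
  expect_error(fit_pipeline(cfg, tbl), "no features survive")
})

test_that("scaler and threshold are fitted on training folds only", {
  # a feature that is constant in training folds but varies in the test fold
  # must not leak: pipeline fits run without using test rows
  tbl <- make_separable_table(n_per_class = 10, shift = 5)
  cfg <- grid_config("standard", 0.001, "KNN", list(nNeighbors = 1, p = 2))
  m1 <- evaluate_config(cfg, tbl, k_folds = 5, seed = 11)
  m2 <- evaluate_config(cfg, tbl, k_folds = 5, seed = 11)
  expect_identical(m1$accuracy, m2$accuracy)  # seed-deterministic folds
})

test_that("hand-rolled KNN agrees with the FNN reference at p = 2", {
  skip_if_not_installed("FNN")
  tbl <- make_separable_table(n_per_class = 25, shift = 1)
  tr <- seq(1, 50, by = 2); te <- seq(2, 50, by = 2)
  m <- fit_classifier("KNN", tbl$x[tr, ], tbl$y[tr], list(nNeighbors = 5, p = 2))
  p <- predict(m, tbl$x[te, ])
  mine <- colnames(p)[max.col(p, ties.method = "first")]
  ref <- as.character(FNN::knn(tbl$x[tr, ], tbl$x[te, ], factor(tbl$y[tr]), k = 5))
  expect_gt(mean(mine == ref), 0.95)
})

test_that("grid search finds and reproduces the best configuration", {
  tbl <- make_separable_table(n_per_class = 15, shift = 6)
  res <- grid_search("KNN", tbl, k_folds = 5, seed = 5,
                     scalers = c("minmax", "maxabs"), thresholds = c(0, 0.01),
                     classifier_grid = list(list(nNeighbors = 1, leafSize = 1, p = 2),
                                            list(nNeighbors = 3, leafSize = 1, p = 1)))
  expect_equal(nrow(res$results), 8)  # 2 grid x 2 scalers x 2 thresholds
  expect_equal(res$best_metrics$accuracy, 1.0)
  re <- evaluate_config(res$best_config, tbl, k_folds = 5, seed = 5)
  expect_equal(re$accuracy, res$best_metrics$accuracy)
  # single-config search returns that config
  solo <- grid_search("NB", tbl, k_folds = 5, seed = 6, scalers = "standard",
                      thresholds = 0, classifier_grid = list(list(alpha = 1)))
  expect_equal(solo$best_config$classifier_params$alpha, 1)
})

test_that("invalid configurations (precomputed kernel) are skipped, not fatal", {
  tbl <- make_separable_table(n_per_class = 10, shift = 6)
  expect_warning(
    res <- grid_search("SVM", tbl, k_folds = 5, seed = 7, scalers = "minmax",
                       thresholds = 0,
                       classifier_grid = list(
                         list(C = 1, kernel = "precomputed", degree = 1, gamma = 1),
                         list(C = 1, kernel = "linear", degree = 1, gamma = 1))),
    "invalid")
  expect_equal(res$best_config$classifier_params$kernel, "linear")
  expect_true(is.na(res$results$accuracy[1]))
})
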