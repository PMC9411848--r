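# Desk-scale end-to-end screening experiment tying the stages together:
# synthesize a labeled voice cohort, segment it, extract the 281-column
# feature table, grid-search a classifier pipeline on the training records,
# and diagnose held-out records through the speech test and score fusion.

#' Run the end-to-end speech screening experiment on a synthetic cohort
#'
#' Patient-level evaluation: records (not segments) are split into train and
#' held-out sets, the pipeline is grid-searched on training segments only,
#' and each held-out record receives a fused diagnosis via [speech_test()]
#' and [fuse()].
#'
#' @param n_per_class records per class (HC / PD).
#' @param duration_s record duration in seconds.
#' @param rate sampling rate in Hz (a low rate keeps the desk-scale run fast).
#' @param durations segmentation durations in seconds.
#' @param seed master seed; drives cohort synthesis, folds and the split.
#' @param k_folds cross-validation folds for the grid search.
#' @param holdout_frac fraction of records per class held out for diagnosis.
#' @param classifier_kind,classifier_grid,scalers,thresholds reduced search
#'   space passed to [grid_search()].
#' @return list: `accuracy` (held-out diagnosis accuracy), `cv_accuracy`
#'   (best grid-search CV accuracy), `best_config`, `decisions` (per-record
#'   data frame), `n_train_records`, `n_test_records`, `n_segments`.
#' @export
run_speech_screening_experiment <- function(
    n_per_class = 8, duration_s = 10, rate = 4000, durations = 5, seed = 1,
    k_folds = 5, holdout_frac = 0.25, classifier_kind = "KNN",
    classifier_grid = list(list(nNeighbors = 1, leafSize = 1, p = 2),
                           list(nNeighbors = 3, leafSize = 1, p = 1)),
    scalers = c("minmax", "maxabs"), thresholds = c(0, 0.01)) {
  records <- c(
    lapply(seq_len(n_per_class), function(i) {
      make_synthetic_audio(duration_s, rate, hc_voice_profile(), label = "HC",
                           record_id = sprintf("HC_%02d", i),
                           seed = derive_seed(seed, i))
    }),
    lapply(seq_len(n_per_class), function(i) {
      make_synthetic_audio(duration_s, rate, pd_voice_profile(), label = "PD",
                           record_id = sprintf("PD_%02d", i),
                           seed = derive_seed(seed, 1000 + i))
    }))
  labels <- vapply(records, `[[`, "", "label")
  test_idx <- withr::with_seed(derive_seed(seed, 2000), {
    unlist(lapply(unique(labels), function(cls) {
      idx <- which(labels == cls)
      idx[sample.int(length(idx), max(1L, round(holdout_frac * length(idx))))]
    }))
  })
  train_records <- records[-test_idx]
  log_stage("workflow", "cohort: %d records (%d held out)", length(records),
            length(test_idx))

  train_segments <- suppressWarnings(
    build_segment_sets(train_records, durations))$combined
  train_table <- build_feature_table(train_segments)
  search <- grid_search(classifier_kind, train_table, k_folds = k_folds,
                        seed = derive_seed(seed, 3000), scalers = scalers,
                        thresholds = thresholds,
                        classifier_grid = classifier_grid)
  pipe <- fit_pipeline(search$best_config, train_table)

  decisions <- do.call(rbind, lapply(test_idx, function(i) {
    rec <- records[[i]]
    score <- suppressMessages(
      speech_test(rec, pipe, durations = durations))
    diag <- suppressMessages(fuse(NA_real_, score, mode = "max"))
    data.frame(record_id = rec$record_id, label = rec$label,
               speech_score = score, decision = diag$decision)
  }))
  list(accuracy = mean(decisions$decision == decisions$label),
       cv_accuracy = search$best_metrics$accuracy,
       best_config = search$best_config, decisions = decisions,
       n_train_records = length(train_records),
       n_test_records = length(test_idx),
       n_segments = length(train_segments))
}
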