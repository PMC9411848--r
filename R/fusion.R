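# Patient-level diagnosis: a handwriting test (three drawn shapes, averaged)
# and a speech test (numeric and graphical classification paths, averaged),
# fused by maximum (or mean) into a single PD score and decision.

#' PD probability mass of a per-class probability vector
#'
#' For 6-class handwriting models the PD mass is the summed probability of
#' the patient classes; for binary models it is the PD column.
#'
#' @param probs named probability vector.
#' @param patient_classes class names counted as PD; defaults to names
#'   starting with "Patient" or equal to "PD".
#' @export
pd_probability_mass <- function(probs, patient_classes = NULL) {
  nms <- names(probs)
  assert_that(!is.null(nms), "probability vector must be named by class")
  if (is.null(patient_classes)) {
    patient_classes <- nms[grepl("^Patient", nms) | nms == "PD"]
  }
  assert_that(length(patient_classes) > 0, "no patient classes identified")
  sum(probs[intersect(nms, patient_classes)])
}

#' Handwriting test: average PD mass over three drawn shapes
#'
#' @param images list of exactly three `image_sample` objects (spiral,
#'   meander, circle).
#' @param classifier either a `pd_cnn_model` or a function mapping an
#'   `image_sample` to a named per-class probability vector.
#' @param patient_classes see [pd_probability_mass()].
#' @return PD score in \[0, 1\].
#' @export
handwriting_test <- function(images, classifier, patient_classes = NULL) {
  assert_that(length(images) == 3, "handwriting test needs exactly 3 images (got %d)",
              length(images))
  score_one <- function(img) {
    probs <- if (is.function(classifier)) classifier(img) else {
      p <- predict_model(classifier, list(img), classes = classifier$classes)
      stats::setNames(as.numeric(p), colnames(p))
    }
    pd_probability_mass(probs, patient_classes)
  }
  mean(vapply(images, score_one, numeric(1)))
}

#' Speech test: averaged numeric and graphical classification paths
#'
#' The record is segmented at the configured durations; the numeric path
#' extracts the feature vector of each segment and averages the classifier's
#' PD probability; the graphical path renders each segment and averages the
#' image model's PD probability. The returned score is the mean of the
#' available path scores (a missing graphical model is allowed, with a
#' caveat message).
#'
#' @param record an `audio_record`.
#' @param numeric_classifier a fitted `pd_pipeline` (see [fit_pipeline()]).
#' @param graph_classifier optional `pd_cnn_model` with `classes` attached,
#'   or NULL to use the numeric path only.
#' @param durations segmentation durations in seconds.
#' @param schema feature schema for the numeric path.
#' @param technique graph technique for the graphical path.
#' @param positive_class class counted as PD (default `"PD"`).
#' @return PD score in \[0, 1\].
#' @export
speech_test <- function(record, numeric_classifier, graph_classifier = NULL,
                        durations = c(5, 15, 30, 60),
                        schema = default_feature_schema(),
                        technique = "mel-specgram", positive_class = "PD") {
  segs <- suppressWarnings(build_segment_sets(list(record), durations))$combined
  assert_that(length(segs) > 0,
              "record '%s' (%.1f s) is shorter than every configured duration",
              record$record_id, record_duration(record))
  tbl <- build_feature_table(segs, schema)
  probs <- predict(numeric_classifier, tbl)
  assert_that(positive_class %in% colnames(probs),
              "numeric classifier does not emit class '%s'", positive_class)
  numeric_score <- mean(probs[, positive_class])
  if (is.null(graph_classifier)) {
    message("speech test: graphical path unavailable; using numeric path only")
    return(numeric_score)
  }
  graph_imgs <- lapply(segs, function(s) {
    g <- render_graph(s, technique)
    image_sample(g$pixels, class_label = s$label)
  })
  gp <- predict_model(graph_classifier, graph_imgs, classes = graph_classifier$classes)
  graph_score <- mean(gp[, positive_class])
  mean(c(numeric_score, graph_score))
}

#' Fuse the two test scores into a diagnosis
#'
#' @param handwriting_score,speech_score PD probabilities in \[0, 1\]; either
#'   (but not both) may be NA when only one modality is available.
#' @param mode `"max"` (default) or `"mean"`.
#' @param threshold decision threshold (default 0.5).
#' @return a `diagnosis_result`: final score, decision (`"PD"`/`"HC"`) and
#'   the per-test breakdown.
#' @export
fuse <- function(handwriting_score, speech_score, mode = c("max", "mean"),
                 threshold = 0.5) {
  mode <- match.arg(mode)
  scores <- c(handwriting = handwriting_score, speech = speech_score)
  avail <- scores[!is.na(scores)]
  assert_that(length(avail) > 0, "at least one test score is required")
  assert_that(all(avail >= 0 & avail <= 1), "scores must lie in [0, 1]")
  if (length(avail) < 2) {
    message("fusion: only the ", names(avail), " test supplied; using it directly")
  }
  final <- if (mode == "max") max(avail) else mean(avail)
  structure(list(handwriting_score = handwriting_score,
                 speech_score = speech_score, fusion_mode = mode,
                 final_score = final,
                 decision = if (final >= threshold) "PD" else "HC",
                 threshold = threshold),
            class = "diagnosis_result")
}

#' @export
print.diagnosis_result <- function(x, ...) {
  cat(sprintf("<diagnosis> handwriting %.3f | speech %.3f | %s -> %.3f => %s\n",
              x$handwriting_score, x$speech_score, x$fusion_mode,
              x$final_score, x$decision))
  invisible(x)
}
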