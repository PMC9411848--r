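# Classification metrics shared by the grid pipeline and the CNN path.
# Micro averaging is the default (for single-label problems micro precision,
# recall, F1 and accuracy coincide); AUC is a one-vs-rest macro average
# computed rank-wise (Mann-Whitney).

confusion_counts <- function(true, pred, classes) {
  table(factor(true, levels = classes), factor(pred, levels = classes),
        dnn = c("true", "pred"))
}

micro_prf <- function(cm) {
  tp <- sum(diag(cm))
  n <- sum(cm)
  acc <- if (n == 0) NA_real_ else tp / n
  # micro: FP and FN both equal n - tp for single-label data
  list(accuracy = acc, precision = acc, recall = acc, f1 = acc)
}

binary_auc <- function(scores, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

auc_ovr_macro <- function(probs, true, classes) {
  aucs <- vapply(seq_along(classes), function(j) {
    binary_auc(probs[, j], true == classes[j])
  }, numeric(1))
  if (all(is.na(aucs))) return(NA_real_)
  mean(aucs, na.rm = TRUE)
}

#' Standard classification metrics from probabilities
#'
#' @param true label vector.
#' @param probs probability matrix with one column per class (class order =
#'   `classes`).
#' @param classes class level vector.
#' @return `metrics_report` list: accuracy / precision / recall / f1
#'   (micro-averaged), auc (one-vs-rest macro), confusion counts.
#' @export
ml_metrics <- function(true, probs, classes) {
  pred <- classes[max.col(probs, ties.method = "first")]
  cm <- confusion_counts(true, pred, classes)
  prf <- micro_prf(cm)
  auc <- auc_ovr_macro(probs, true, classes)
  if (is.na(auc)) {
    warning("AUC undefined on a degenerate (single-class) evaluation; recording 0.5")
    auc <- 0.5
  }
  structure(c(prf, list(auc = auc, confusion = cm)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f | AUC %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1, x$auc))
  invisible(x)
}

#' Extended metric set for the CNN path
#'
#' Micro-averaged accuracy/precision/recall/F1 and specificity from argmax
#' predictions, one-vs-rest macro AUC, and IOU / Dice overlap between the
#' 0.5-thresholded probability mass and the one-hot truth (micro-summed over
#' the batch) — the overlap convention for single-label classification is a
#' package choice, documented in the vignette.
#'
#' @param true_onehot n x k one-hot matrix.
#' @param probs n x k probability matrix, rows summing to 1.
#' @param loss optional training-loss value carried through.
#' @return `extended_metrics` list.
#' @export
extended_metrics <- function(true_onehot, probs, loss = NA_real_) {
  assert_that(all(dim(true_onehot) == dim(probs)),
              "true/predicted shape mismatch: %s vs %s",
              paste(dim(true_onehot), collapse = "x"),
              paste(dim(probs), collapse = "x"))
  k <- ncol(probs)
  classes <- colnames(probs) %||% as.character(seq_len(k))
  true_idx <- max.col(true_onehot, ties.method = "first")
  pred_idx <- max.col(probs, ties.method = "first")
  cm <- confusion_counts(classes[true_idx], classes[pred_idx], classes)
  prf <- micro_prf(cm)
  # micro specificity over one-vs-rest negatives
  n <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- n - tp - fp - fn
  specificity <- sum(tn) / max(sum(tn) + sum(fp), 1)
  auc <- auc_ovr_macro(probs, classes[true_idx], classes)
  if (is.na(auc)) auc <- 0.5
  pred_bin <- probs >= 0.5
  inter <- sum(pred_bin & (true_onehot > 0.5))
  uni <- sum(pred_bin | (true_onehot > 0.5))
  iou <- if (uni == 0) 1 else inter / uni
  dice_den <- sum(pred_bin) + sum(true_onehot > 0.5)
  dice <- if (dice_den == 0) 1 else 2 * inter / dice_den
  structure(list(loss = loss, accuracy = prf$accuracy, f1 = prf$f1,
                 precision = prf$precision, recall = prf$recall,
                 specificity = specificity, auc = auc,
                 iou_coef = iou, dice_coef = dice, confusion = cm),
            class = "extended_metrics")
}

#' @export
print.extended_metrics <- function(x, ...) {
  cat(sprintf(paste0("loss %.4f | acc %.4f | F1 %.4f | prec %.4f | rec %.4f | ",
                     "spec %.4f | AUC %.4f | IOU %.4f | Dice %.4f\n"),
              x$loss, x$accuracy, x$f1, x$precision, x$recall,
              x$specificity, x$auc, x$iou_coef, x$dice_coef))
  invisible(x)
}
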