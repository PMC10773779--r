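## Binary-classification metric suite. Positive class = 1 = poor prognosis.

#' Confusion counts
#'
#' @param y_true,y_pred equal-length binary (0/1) vectors; 1 = poor prognosis.
#' @return A `"confusion_counts"` list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stopf("y_true and y_pred lengths differ (%d vs %d)",
          length(y_true), length(y_pred))
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stopf("labels and predictions must be binary 0/1")
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 FP = sum(y_true == 0 & y_pred == 1),
                 TN = sum(y_true == 0 & y_pred == 0),
                 FN = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

#' F1 score from precision and sensitivity
#'
#' Harmonic mean `2 * p * r / (p + r)`; accepts percentages or proportions.
#' @param precision,sensitivity positive reals.
#' @return F1 on the same scale as the inputs.
#' @export
f1_score <- function(precision, sensitivity) {
  2 * precision * sensitivity / (precision + sensitivity)
}

#' Compute the metric suite from confusion counts
#'
#' accuracy = (TP+TN)/total, precision = TP/(TP+FP),
#' sensitivity (recall) = TP/(TP+FN), specificity = TN/(TN+FP),
#' F1 = harmonic mean of precision and sensitivity. A zero denominator yields
#' `NA` and the metric's name is recorded in the `undefined` field (silent
#' zeros would corrupt cross-validation means).
#'
#' @param counts a [confusion_counts()] object (or list with TP/FP/TN/FN).
#' @return A `"metric_report"` list with the five metrics, the counts and
#'   `undefined`.
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0) stopf("all confusion counts are zero")
  undef <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(NA_real_) }
    num / den
  }
  acc <- (TP + TN) / total
  prec <- safe(TP, TP + FP, "precision")
  sens <- safe(TP, TP + FN, "sensitivity")
  spec <- safe(TN, TN + FP, "specificity")
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) {
    undef <- c(undef, "f1"); NA_real_
  } else f1_score(prec, sens)
  structure(list(accuracy = acc, precision = prec, sensitivity = sens,
                 specificity = spec, f1 = f1,
                 counts = list(TP = TP, FP = FP, TN = TN, FN = FN),
                 undefined = undef),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %s  sensitivity %s  specificity %s  F1 %s\n",
              x$accuracy, format(x$precision, digits = 4),
              format(x$sensitivity, digits = 4),
              format(x$specificity, digits = 4), format(x$f1, digits = 4)))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) estimator with midrank tie correction: the probability
#' that a random positive outscores a random negative, ties counting one half.
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric scores (higher = more poor-prognosis-like).
#' @param labels binary 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stopf("roc_auc needs both classes present (got %d positives, %d negatives)",
          n1, n0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#' @param scores,labels as in [roc_auc()].
#' @return data frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tpr <- vapply(th, function(t) sum(scores >= t & labels == 1) / n1, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & labels == 0) / n0, numeric(1))
  data.frame(threshold = th, fpr = fpr, tpr = tpr)
}
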