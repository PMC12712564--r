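# Binary classification metrics on predicted probabilities. All metrics lie
# in [0, 1]; cells that are genuinely undefined (e.g. a single-class test
# set for a ranking metric) return NA rather than 0.

#' Area under the ROC curve
#'
#' Rank statistic (Mann-Whitney) formulation with midrank tie handling.
#'
#' @param scores predicted probabilities of the positive class.
#' @param labels binary 0/1 labels.
#' @return AUC in [0, 1], or NA if only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-function average precision: sum over descending score thresholds of
#' the recall increment times the precision at that threshold.
#'
#' @inheritParams roc_auc
#' @return average precision in [0, 1], or NA if no positives.
#' @export
pr_auc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # Evaluate at the last index of each distinct score (ties grouped).
  last <- which(!duplicated(s, fromLast = TRUE))
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / n1
  sum(diff(c(0, rec)) * prec)
}

# Confusion counts at a fixed threshold (prediction positive iff
# score >= threshold).
confusion_at <- function(scores, labels, threshold) {
  pred <- as.integer(scores >= threshold)
  c(tp = sum(pred == 1 & labels == 1), fp = sum(pred == 1 & labels == 0),
    fn = sum(pred == 0 & labels == 1), tn = sum(pred == 0 & labels == 0))
}

#' Thresholded classification metrics
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold; prediction positive iff
#'   score >= threshold.
#' @param metric one of `"precision"`, `"recall"`, `"accuracy"`,
#'   `"macro_f1"`. Precision with no predicted positives is reported as 0
#'   (documented convention); per-class F1 with a zero denominator
#'   contributes 0 to the macro average.
#' @return metric value in [0, 1].
#' @export
thresholded_metric <- function(scores, labels, threshold,
                               metric = c("precision", "recall", "accuracy",
                                          "macro_f1")) {
  metric <- match.arg(metric)
  cm <- confusion_at(scores, labels, threshold)
  tp <- cm["tp"]; fp <- cm["fp"]; fn <- cm["fn"]; tn <- cm["tn"]
  unname(switch(metric,
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    accuracy = (tp + tn) / sum(cm),
    macro_f1 = {
      f1_pos <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
      f1_neg <- if (2 * tn + fp + fn == 0) 0 else 2 * tn / (2 * tn + fp + fn)
      (f1_pos + f1_neg) / 2
    }
  ))
}

# Dispatch for interyear evaluation.
compute_metric <- function(metric, scores, labels, threshold) {
  switch(metric,
    roc_auc = roc_auc(scores, labels),
    pr_auc = pr_auc(scores, labels),
    thresholded_metric(scores, labels, threshold, metric)
  )
}

metric_names <- function() {
  c("roc_auc", "pr_auc", "precision", "recall", "accuracy", "macro_f1")
}
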