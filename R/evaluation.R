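#' Confusion counts at a threshold
#'
#' A sample is predicted positive iff its score is >= `threshold` (closed
#' lower bound). TPR = TP/(TP+FN) and FPR = FP/(FP+TN); both classes must be
#' present, otherwise the corresponding rate is undefined and an error is
#' raised.
#'
#' @param scores finite numeric scores.
#' @param labels binary 0/1 labels.
#' @param threshold decision threshold.
#' @return List with `TP`, `FP`, `TN`, `FN`, `tpr`, `fpr`.
#' @export
confusion_at <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  labels <- as.integer(labels)
  if (!all(labels %in% 0:1)) stop("labels must be binary 0/1")
  if (!any(labels == 1L)) stop("no positive samples: TPR undefined")
  if (!any(labels == 0L)) stop("no negative samples: FPR undefined")
  pred <- scores >= threshold
  TP <- sum(pred & labels == 1L); FP <- sum(pred & labels == 0L)
  FN <- sum(!pred & labels == 1L); TN <- sum(!pred & labels == 0L)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       tpr = TP / (TP + FN), fpr = FP / (FP + TN))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic P(score_pos > score_neg) +
#' 0.5 P(tie) via average ranks, which equals trapezoidal integration of the
#' all-thresholds ROC curve.
#'
#' @param scores finite numeric scores.
#' @param labels binary 0/1 labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) stop("both classes required for AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-linear) interpolation: thresholds sweep every distinct
#' score in descending order and each recall increment contributes its
#' precision as a rectangle, i.e. average precision. Linear interpolation
#' between PR points is deliberately not used, as it over-estimates the area.
#'
#' @param scores finite numeric scores.
#' @param labels binary 0/1 labels; positives must be present.
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0) stop("positives required for AUPRC")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)      # last index of each distinct score
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' ROC and precision-recall curves with areas
#'
#' Thresholds are the distinct scores in descending order (plus +Inf anchor),
#' predictions use score >= threshold. The ROC curve is anchored at (0, 0)
#' and (1, 1); precision/recall are reported at every threshold.
#'
#' @param scores finite numeric scores.
#' @param labels binary 0/1 labels, both classes present.
#' @return An `eval_curves` list: `thresholds`, `tpr`, `fpr`, `precision`,
#'   `recall`, `auroc`, `auprc`.
#' @export
eval_curves <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) stop("both classes required")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)
  thr <- c(Inf, s[last])
  tp <- c(0, tp[last]); fp <- c(0, fp[last])
  structure(list(thresholds = thr, tpr = tp / n_pos, fpr = fp / n_neg,
                 precision = ifelse(tp + fp > 0, tp / (tp + fp), 1),
                 recall = tp / n_pos,
                 auroc = auroc(scores, labels),
                 auprc = auprc(scores, labels)),
            class = "eval_curves")
}
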