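# Evaluation metrics: Dice / precision / recall on hard masks, confusion
# matrix ratios (accuracy, recall, specificity) and ROC/AUC by threshold
# sweep with trapezoidal integration.

#' Dice coefficient between two binary masks
#'
#' `2 |T intersect P| / (|T| + |P|)`; 1 for a perfect match.
#'
#' @param P predicted binary mask.
#' @param T_ ground-truth binary mask of the same shape.
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(P, T_) {
  P <- as.numeric(as_any_mask(P)); T_ <- as.numeric(as_any_mask(T_))
  if (length(P) != length(T_)) stop("P and T must have the same shape")
  sp <- sum(P); st <- sum(T_)
  if (sp + st == 0) stop("Dice undefined: both masks empty")
  2 * sum(P * T_) / (sp + st)
}

as_any_mask <- function(m) {
  if (inherits(m, "binary_mask")) return(unclass(m))
  if (is.logical(m)) return(m * 1L)
  m
}

#' Precision and recall of a predicted mask
#'
#' Precision = `|T intersect P| / |P|`; recall = `|T intersect P| / |T|`.
#' An empty denominator mask makes the metric undefined and is reported as
#' `NA`.
#'
#' @param P predicted binary mask.
#' @param T_ ground-truth binary mask.
#' @return scalar in `[0, 1]` or `NA`.
#' @export
precision_metric <- function(P, T_) {
  P <- as.numeric(as_any_mask(P)); T_ <- as.numeric(as_any_mask(T_))
  if (sum(P) == 0) return(NA_real_)
  sum(P * T_) / sum(P)
}

#' @rdname precision_metric
#' @export
recall_metric <- function(P, T_) {
  P <- as.numeric(as_any_mask(P)); T_ <- as.numeric(as_any_mask(T_))
  if (sum(T_) == 0) return(NA_real_)
  sum(P * T_) / sum(T_)
}

#' Confusion matrix counts
#'
#' @param TP,FP,TN,FN non-negative integer counts, total >= 1.
#' @return A `confusion_matrix` list.
#' @export
confusion_matrix <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || sum(counts) < 1) {
    stop("counts must be non-negative with total >= 1")
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' Accuracy, recall and specificity from a confusion matrix
#'
#' Accuracy = (TP+TN)/total, recall = TP/(TP+FN), specificity = TN/(FP+TN).
#' Metrics with an empty denominator are `NA`.
#'
#' @param cm a [confusion_matrix()].
#' @return named list (accuracy, recall, specificity).
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$FP + cm$TN + cm$FN
  list(accuracy = (cm$TP + cm$TN) / total,
       recall = if (cm$TP + cm$FN > 0) cm$TP / (cm$TP + cm$FN) else NA_real_,
       specificity = if (cm$FP + cm$TN > 0) cm$TN / (cm$FP + cm$TN) else NA_real_)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (descending); the curve is the
#' set of (FPR, TPR) points and the AUC its trapezoidal area, which equals
#' the pairwise rank statistic (ties between a positive and a negative
#' score receive half credit).
#'
#' @param scores numeric scores in `[0, 1]` (probability of the positive
#'   class).
#' @param labels 0/1 labels; both classes must be present.
#' @return list with `curve` (data.frame fpr, tpr, threshold) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels != 0)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("ROC needs both classes present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / np, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / nn, 0)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}
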