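#' Binary classification metrics
#'
#' Thresholded confusion-table metrics plus AUC. Accuracy, precision,
#' sensitivity (recall), specificity and F1 follow the standard definitions
#' \deqn{Accuracy = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{Precision = TP/(TP+FP), \quad Sensitivity = TP/(TP+FN)}
#' \deqn{Specificity = TN/(TN+FP), \quad F1 = 2 P S/(P+S)}
#' and AUC is the Mann-Whitney rank statistic (equal to the trapezoidal area
#' under the ROC curve, with ties counted half). Metrics with a zero
#' denominator are reported as `NaN` and listed in `undefined_metrics`,
#' never silently set to 0.
#'
#' @param labels Binary ground-truth labels.
#' @param probabilities Scores/probabilities in `[0, 1]`.
#' @param threshold Decision threshold for the confusion table (default 0.5;
#'   probability >= threshold predicts class 1).
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `f1`, `auc`, `n`, and `undefined_metrics`
#'   (comma-separated names, empty string when all are defined).
#' @export
compute_metrics <- function(labels, probabilities, threshold = 0.5) {
  labels <- as_binary_labels(labels)
  stopifnot(length(labels) == length(probabilities))
  if (any(probabilities < -1e-12 | probabilities > 1 + 1e-12)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  safe_div <- function(num, den) if (den == 0) NaN else num / den
  precision <- safe_div(tp, tp + fp)
  sensitivity <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- if (is.nan(precision) || is.nan(sensitivity) ||
            (precision + sensitivity) == 0) {
    NaN
  } else {
    2 * precision * sensitivity / (precision + sensitivity)
  }
  auc <- auc_score(labels, probabilities)
  vals <- c(accuracy = safe_div(tp + tn, length(labels)),
            precision = precision, sensitivity = sensitivity,
            specificity = specificity, f1 = f1, auc = auc)
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = vals[["accuracy"]], precision = vals[["precision"]],
                 sensitivity = vals[["sensitivity"]],
                 specificity = vals[["specificity"]],
                 f1 = vals[["f1"]], auc = vals[["auc"]], n = length(labels),
                 undefined_metrics = paste(names(vals)[is.nan(vals)],
                                           collapse = ","))
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney form: the proportion of (positive, negative) pairs ranked
#' correctly, ties counted 1/2; identical to the trapezoid area under the
#' ROC curve.
#'
#' @param labels Binary labels.
#' @param probabilities Scores.
#' @return AUC in `[0, 1]`; `NaN` if a class is absent.
#' @export
auc_score <- function(labels, probabilities) {
  labels <- as_binary_labels(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NaN)
  r <- rank(probabilities)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-table metrics from counts
#'
#' Direct evaluation of the metric formulas from the four confusion counts;
#' convenience for reporting and testing.
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @return One-row tibble as in [compute_metrics()] minus `auc`.
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  labels <- c(rep(1, tp + fn), rep(0, tn + fp))
  probs <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
  out <- compute_metrics(labels, probs)
  out$auc <- NULL
  out
}
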