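#' Six-metric classification report
#'
#' Thresholds the predicted probabilities (default 0.5, predictions at the
#' threshold count as positive) into a confusion matrix and reports
#' accuracy, sensitivity (recall), precision, specificity, F1 (harmonic mean
#' of precision and sensitivity) and AUC by trapezoidal integration of the
#' ROC curve.  Metrics with a zero denominator are reported as `NA` with a
#' warning naming the degenerate count; AUC with single-class labels is an
#' error.
#'
#' @param labels Binary labels (0/1).
#' @param probs Predicted probabilities or scores.
#' @param threshold Decision threshold for the confusion-based metrics.
#' @return A one-row tibble: `accuracy`, `sensitivity`, `precision`,
#'   `specificity`, `f1`, `auc`, `tp`, `fp`, `tn`, `fn`, `n`.
#' @export
#' @examples
#' compute_metrics(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
#'                 c(.9, .8, .7, .4, .3, .6, .2, .2, .1, .1))
compute_metrics <- function(labels, probs, threshold = 0.5) {
  if (length(labels) != length(probs)) {
    abort("`labels` and `probs` must have equal length.")
  }
  if (!all(labels %in% c(0, 1))) abort("`labels` must be binary 0/1.")
  if (length(unique(labels)) < 2) {
    abort("AUC is undefined: only one class present in `labels`.")
  }
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s is undefined: its denominator count is zero.", what))
      return(NA_real_)
    }
    num / den
  }
  sens <- safe_div(tp, tp + fn, "sensitivity")
  prec <- safe_div(tp, tp + fp, "precision")
  spec <- safe_div(tn, tn + fp, "specificity")
  f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  tibble(accuracy = (tp + tn) / length(labels),
         sensitivity = sens, precision = prec, specificity = spec,
         f1 = f1, auc = roc_auc(labels, probs),
         tp = tp, fp = fp, tn = tn, fn = fn, n = length(labels))
}

#' ROC curve points
#'
#' One (FPR, TPR) point per distinct score threshold (ties grouped),
#' anchored at (0, 0) and (1, 1).
#'
#' @param labels Binary labels.
#' @param probs Scores.
#' @return A tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(labels, probs) {
  ord <- order(probs, decreasing = TRUE)
  labels <- labels[ord]; probs <- probs[ord]
  grp <- cumsum(!duplicated(probs))
  tp <- tapply(labels == 1, grp, sum)
  fp <- tapply(labels == 0, grp, sum)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  tibble(threshold = c(Inf, probs[!duplicated(probs)]),
         fpr = unname(c(0, cumsum(fp) / n_neg)),
         tpr = unname(c(0, cumsum(tp) / n_pos)))
}

#' Area under the ROC curve by trapezoidal integration
#'
#' @param labels Binary labels (both classes must be present).
#' @param probs Scores.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, probs) {
  if (length(unique(labels)) < 2) {
    abort("AUC is undefined: only one class present in `labels`.")
  }
  pts <- roc_points(labels, probs)
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
}
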