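#' Confusion-matrix metrics at a threshold
#'
#' Scores greater than or equal to the threshold are called positive.
#' Returns Matthews correlation coefficient, accuracy, precision and
#' recall; MCC is defined as 0 whenever a marginal of the confusion matrix
#' is zero (the standard convention for the degenerate denominator), and
#' precision/recall are 0 when undefined.
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric vector aligned with `labels`.
#' @param threshold decision threshold.
#' @return Named list: `mcc`, `accuracy`, `precision`, `recall`, and the
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("empty input")
  if (length(labels) != length(scores)) stop("labels/scores length mismatch")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  list(
    mcc = mcc,
    accuracy = (tp + tn) / length(labels),
    precision = if (tp + fp == 0L) 0 else tp / (tp + fp),
    recall = if (tp + fn == 0L) 0 else tp / (tp + fn),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

# threshold sweep shared by the ROC and PR curves: descending unique scores,
# cumulative TP/FP counts (ties grouped)
sweep_counts_ <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to sweep thresholds")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last_of_tie <- which(c(diff(s) != 0, TRUE))
  tp <- cumsum(l)[last_of_tie]
  fp <- cumsum(1L - l)[last_of_tie]
  list(tp = tp, fp = fp, thresholds = s[last_of_tie],
       P = sum(l), N = sum(1L - l))
}

#' ROC curve and area
#'
#' Thresholds sweep the unique score values (score >= threshold called
#' positive); the area is computed by trapezoidal integration and equals
#' the concordance probability with ties counted one half.
#'
#' @inheritParams confusion_metrics
#' @return list with a `curve` data frame (threshold, fpr, tpr) and `auc`.
#' @export
roc_curve <- function(labels, scores) {
  cnt <- sweep_counts_(labels, scores)
  tpr <- c(0, cnt$tp / cnt$P)
  fpr <- c(0, cnt$fp / cnt$N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(
    curve = data.frame(threshold = c(Inf, cnt$thresholds), fpr = fpr,
                       tpr = tpr),
    auc = auc
  )
}

#' Precision-recall curve and area
#'
#' Same threshold sweep as [roc_curve()]. The reported area integrates the
#' monotone-interpolated curve (precision replaced by the running maximum
#' from the high-recall end) by trapezoids over recall — interpolation
#' conventions differ between tools, so the choice is stated here.
#'
#' @inheritParams confusion_metrics
#' @return list with a `curve` data frame (threshold, recall, precision,
#'   precision_interp) and `auc`.
#' @export
pr_curve <- function(labels, scores) {
  cnt <- sweep_counts_(labels, scores)
  recall <- cnt$tp / cnt$P
  precision <- cnt$tp / (cnt$tp + cnt$fp)
  # prepend the zero-recall anchor at the first point's precision
  recall <- c(0, recall)
  precision <- c(precision[1L], precision)
  thresholds <- c(Inf, cnt$thresholds)
  interp <- rev(cummax(rev(precision)))
  auc <- sum(diff(recall) * (head(interp, -1) + interp[-1]) / 2)
  list(
    curve = data.frame(threshold = thresholds, recall = recall,
                       precision = precision, precision_interp = interp),
    auc = auc
  )
}

#' MCC-maximizing threshold
#'
#' Exhaustive scan over the midpoints of consecutive unique score values
#' (with a single unique score, that score itself is the only candidate).
#' Ties are broken toward the smaller threshold.
#'
#' @inheritParams confusion_metrics
#' @return list with `threshold` and `mcc`.
#' @export
best_mcc_threshold <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to choose a threshold")
  }
  u <- sort(unique(scores))
  candidates <- if (length(u) == 1L) u else (head(u, -1) + u[-1]) / 2
  mccs <- vapply(candidates,
                 function(t) confusion_metrics(labels, scores, t)$mcc,
                 numeric(1))
  best <- which.max(mccs)  # first max -> smallest threshold on ties
  list(threshold = candidates[best], mcc = mccs[best])
}

#' Full metrics report
#'
#' The testing-set battery: MCC, accuracy, precision and recall at the
#' MCC-maximizing threshold (or a fixed threshold when given), plus the
#' ROC and PR areas.
#'
#' @inheritParams confusion_metrics
#' @param threshold fixed decision threshold; `NULL` (default) uses the
#'   MCC-maximizing threshold.
#' @return A list of class `metrics_report`.
#' @export
metrics_report <- function(labels, scores, threshold = NULL) {
  if (is.null(threshold)) {
    threshold <- best_mcc_threshold(labels, scores)$threshold
  }
  cm <- confusion_metrics(labels, scores, threshold)
  structure(
    list(mcc = cm$mcc, accuracy = cm$accuracy, precision = cm$precision,
         recall = cm$recall, roc_auc = roc_curve(labels, scores)$auc,
         pr_auc = pr_curve(labels, scores)$auc,
         threshold_at_max_mcc = threshold),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    paste0("<metrics_report: MCC %.3f  ACC %.3f  precision %.3f  ",
           "recall %.3f  ROC-auc %.3f  PR-auc %.3f  (thr %.3f)>\n"),
    x$mcc, x$accuracy, x$precision, x$recall, x$roc_auc, x$pr_auc,
    x$threshold_at_max_mcc
  ))
  invisible(x)
}

#' Plot ROC and PR curves
#'
#' Base-graphics rendering of the two evaluation curves side by side, with
#' areas in the legend.
#'
#' @inheritParams confusion_metrics
#' @export
plot_eval_curves <- function(labels, scores) {
  roc <- roc_curve(labels, scores)
  pr <- pr_curve(labels, scores)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(roc$curve$fpr, roc$curve$tpr, type = "l", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (auc = %.3f)", roc$auc))
  graphics::abline(0, 1, lty = 3)
  graphics::plot(pr$curve$recall, pr$curve$precision, type = "l", lwd = 2,
                 xlab = "Recall", ylab = "Precision", ylim = c(0, 1),
                 main = sprintf("PR (auc = %.3f)", pr$auc))
  invisible(list(roc = roc, pr = pr))
}
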