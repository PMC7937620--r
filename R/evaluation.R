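#' Confusion matrix and threshold metrics
#'
#' Predicts positive when `score >= threshold` and tabulates the 2x2
#' confusion matrix together with accuracy, precision (PPV), recall
#' (TPR), specificity (TNR) and F1. Ratios that are undefined (0/0) are
#' reported as 0 and flagged in `undefined`.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels 0/1 labels aligned with `scores`.
#' @param threshold Decision threshold in `[0, 1]`.
#' @return List with `confusion` (2x2 integer matrix), `accuracy`,
#'   `precision`, `recall`, `specificity`, `f1`, `threshold`, `undefined`.
#' @export
confusion_at <- function(scores, labels, threshold) {
  if (length(scores) == 0) stop("empty input")
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  pred <- as.integer(scores >= threshold)
  labels <- as.integer(labels)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  safe <- function(num, den) if (den == 0) 0 else num / den
  undefined <- character(0)
  if (tp + fp == 0) undefined <- c(undefined, "precision")
  if (tp + fn == 0) undefined <- c(undefined, "recall")
  if (tn + fp == 0) undefined <- c(undefined, "specificity")
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  if (precision + recall == 0) undefined <- c(undefined, "f1")
  list(
    confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                       dimnames = list(truth = c("pos", "neg"),
                                       predicted = c("pos", "neg"))),
    accuracy = (tp + tn) / length(labels),
    precision = precision,
    recall = recall,
    specificity = safe(tn, tn + fp),
    f1 = safe(2 * precision * recall, precision + recall),
    threshold = threshold,
    undefined = undefined
  )
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores, collects
#' (FPR, TPR) points from (0,0) to (1,1) and integrates with the
#' trapezoidal rule. The result equals the rank statistic: the
#' probability that a random positive outscores a random negative, with
#' ties counted half.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return List with `roc` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # collapse tied scores: one ROC point per unique threshold
  last <- cumsum(rle(s)$lengths)
  tpr <- c(0, cumsum(y)[last] / n_pos)
  fpr <- c(0, cumsum(1 - y)[last] / n_neg)
  thr <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}

#' Least-error decision threshold
#'
#' Scans candidate thresholds — the smallest score (predict everything
#' positive), the midpoints between consecutive unique scores, and one
#' value above the maximum (predict everything negative) — and returns
#' the one with the fewest misclassifications; ties go to the smallest
#' threshold.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return List with `threshold` and `error` (misclassification rate).
#' @export
best_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  u <- sort(unique(scores))
  cand <- c(u[1],
            if (length(u) > 1) (utils::head(u, -1) + utils::tail(u, -1)) / 2,
            u[length(u)] + 1)
  errs <- vapply(cand, function(t) sum((scores >= t) != (labels == 1)),
                 numeric(1))
  i <- which.min(errs)  # which.min takes the first (smallest) on ties
  list(threshold = cand[i], error = errs[i] / length(labels))
}

#' Full evaluation report for one score vector
#'
#' Combines the ROC curve, AUC, the least-error threshold and the
#' confusion-matrix metrics at that threshold (or a caller-supplied one).
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels 0/1 labels.
#' @param threshold Optional fixed threshold; default: [best_threshold()].
#' @return An object of class `evaluation_report`.
#' @export
evaluate_scores <- function(scores, labels, threshold = NULL) {
  roc <- roc_auc(scores, labels)
  bt <- best_threshold(scores, labels)
  if (is.null(threshold)) threshold <- bt$threshold
  cm <- confusion_at(scores, labels, threshold)
  structure(
    c(cm, list(roc = roc$roc, auc = roc$auc,
               best_threshold = bt$threshold, best_error = bt$error)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report: n=%d  acc=%.4f  prec=%.4f  rec=%.4f  f1=%.4f  auc=%.4f  thr=%.4g\n",
    sum(x$confusion), x$accuracy, x$precision, x$recall, x$f1, x$auc,
    x$threshold
  ))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `report.json` (scalar metrics), `roc.tsv` (fpr, tpr, threshold)
#' and `confusion.tsv` into `dir`, so curves can be replotted without
#' rerunning the classifier.
#'
#' @param report An [evaluate_scores()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- report[c("accuracy", "precision", "recall", "specificity",
                      "f1", "auc", "threshold", "best_threshold",
                      "best_error")]
  jsonlite::write_json(metrics, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(report$roc, file.path(dir, "roc.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(report$confusion),
                     file.path(dir, "confusion.tsv"), sep = "\t",
                     quote = FALSE)
  invisible(dir)
}
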