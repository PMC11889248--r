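# Evaluation metrics: balanced accuracy (Avg_Acc), per-class F1 and ROC-AUC.

.check_binary_labels <- function(labels) {
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1)) || length(u) < 2L)
    stop("labels must contain both classes 0 and 1", call. = FALSE)
  invisible(u)
}

#' Balanced accuracy (Avg_Acc)
#'
#' The mean of the per-class recalls. Under heavy class imbalance this is the
#' honest summary: a constant classifier scores exactly 0.5 on any two-class
#' set, regardless of the class ratio.
#'
#' @param labels True labels, coded 0/1; both classes must be present.
#' @param predictions Predicted labels, coded 0/1.
#' @return A number in `[0, 1]`.
#' @examples
#' balanced_accuracy(c(0, 0, 0, 1), c(0, 0, 1, 1))  # (2/3 + 1)/2
#' @export
balanced_accuracy <- function(labels, predictions) {
  .check_binary_labels(labels)
  mean(vapply(c(0, 1), function(k) mean(predictions[labels == k] == k), 0))
}

#' Per-class and macro F1 scores
#'
#' Standard harmonic mean of precision and recall, computed per class from
#' the confusion table, plus their unweighted (macro) average. When a class
#' is never predicted its precision is undefined; its F1 is reported as 0
#' with a warning, the usual degenerate-predictor convention.
#'
#' @inheritParams balanced_accuracy
#' @return A list with `macro` (scalar) and `per_class` (named length-2
#'   vector, classes "0" and "1").
#' @export
f1_scores <- function(labels, predictions) {
  .check_binary_labels(labels)
  per <- vapply(c(0, 1), function(k) {
    tp <- sum(labels == k & predictions == k)
    fp <- sum(labels != k & predictions == k)
    fn <- sum(labels == k & predictions != k)
    if (tp + fp == 0) {
      warning(sprintf("class %d never predicted; its F1 is set to 0", k),
              call. = FALSE)
      return(0)
    }
    if (tp == 0) return(0)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, 0)
  names(per) <- c("0", "1")
  list(macro = mean(per), per_class = per)
}

#' Area under the ROC curve
#'
#' Computed with the rank (Wilcoxon/Mann-Whitney) formula using midranks, so
#' tied scores contribute half a win; equal to the probability that a random
#' positive outscores a random negative. Invariant under any strictly
#' monotone transform of the scores.
#'
#' @param labels True labels, coded 0/1; both classes must be present.
#' @param scores Continuous positive-class scores.
#' @return A number in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  .check_binary_labels(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Assemble a full metrics report
#'
#' Computes the confusion table, balanced accuracy, per-class recalls,
#' per-class and macro F1, and ROC-AUC for one evaluation pass.
#'
#' @inheritParams balanced_accuracy
#' @param scores Positive-class scores for the ROC-AUC (e.g. softmax
#'   probabilities); when `NULL` the hard predictions are used, which
#'   degrades the AUC to its tie-corrected step approximation.
#' @return An object of class `metrics_report`: a list with `avg_acc`,
#'   `per_class_recall`, `f1` (macro), `f1_per_class`, `roc_auc`,
#'   `confusion` (2x2 integer table, truth in rows) and `n`.
#' @export
metrics_report <- function(labels, predictions, scores = NULL) {
  .check_binary_labels(labels)
  if (is.null(scores)) scores <- predictions
  conf <- table(factor(labels, levels = c(0, 1)),
                factor(predictions, levels = c(0, 1)),
                dnn = c("truth", "predicted"))
  rec <- vapply(c(0, 1), function(k) mean(predictions[labels == k] == k), 0)
  names(rec) <- c("0", "1")
  f1 <- suppressWarnings(f1_scores(labels, predictions))
  structure(list(avg_acc = mean(rec), per_class_recall = rec,
                 f1 = f1$macro, f1_per_class = f1$per_class,
                 roc_auc = roc_auc(labels, scores),
                 confusion = conf, n = length(labels)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Avg_Acc %.4f | F1 (macro) %.4f | ROC-AUC %.4f | n = %d\n",
              x$avg_acc, x$f1, x$roc_auc, x$n))
  cat(sprintf("recall: normal %.4f, micronucleus %.4f\n",
              x$per_class_recall[["0"]], x$per_class_recall[["1"]]))
  print(x$confusion)
  invisible(x)
}
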