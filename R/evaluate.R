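# Evaluation with abnormal as the positive class: confusion counts, the four
# threshold metrics, and rank-based (Mann-Whitney) AUC.

#' Confusion counts with abnormal as positive
#'
#' @param true_labels,pred_labels Character vectors in
#'   `{"normal", "abnormal"}`, equal length.
#' @return Named integer vector `c(TP, TN, FP, FN)` partitioning the input.
#' @export
confusion <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels))
    stopf("label vectors must have equal length")
  ok <- c("normal", "abnormal")
  bad <- setdiff(unique(c(true_labels, pred_labels)), ok)
  if (length(bad))
    stopf("unknown label value(s): %s", paste(bad, collapse = ", "))
  c(TP = sum(true_labels == "abnormal" & pred_labels == "abnormal"),
    TN = sum(true_labels == "normal" & pred_labels == "normal"),
    FP = sum(true_labels == "normal" & pred_labels == "abnormal"),
    FN = sum(true_labels == "abnormal" & pred_labels == "normal"))
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' `acc = (TP+TN)/n`, `pre = TP/(TP+FP)`, `rec = TP/(TP+FN)`,
#' `f1 = 2 pre rec / (pre + rec)`. A metric whose denominator is zero is
#' reported as `NA` with its name listed in the `undefined` attribute, never
#' silently as 0.
#'
#' @param counts Named vector with `TP`, `TN`, `FP`, `FN` (see [confusion()]).
#' @return Named numeric vector `c(acc, pre, rec, f1)`; attribute `undefined`
#'   names any metric with a zero denominator.
#' @export
metrics <- function(counts) {
  need <- c("TP", "TN", "FP", "FN")
  if (!all(need %in% names(counts))) stopf("counts must contain TP/TN/FP/FN")
  counts <- counts[need]
  n <- sum(counts)
  if (n == 0) stopf("all counts are zero")
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  undefined <- character(0)
  acc <- (tp + counts[["TN"]]) / n
  pre <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "pre"); NA_real_ }
  rec <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "rec"); NA_real_ }
  f1 <- if (!is.na(pre) && !is.na(rec) && pre + rec > 0)
    2 * pre * rec / (pre + rec)
  else { undefined <- c(undefined, "f1"); NA_real_ }
  structure(c(acc = acc, pre = pre, rec = rec, f1 = f1),
            undefined = undefined)
}

#' Rank-based AUC of anomaly scores
#'
#' The Mann-Whitney statistic: the fraction of (abnormal, normal) pairs in
#' which the abnormal beat scores strictly higher, ties counted 1/2 -- i.e.
#' the probability that a random abnormal beat outscores a random normal one,
#' equal to the area under the ROC curve and invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores Numeric anomaly scores.
#' @param true_labels Labels in `{"normal", "abnormal"}`; both classes must
#'   be present.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, true_labels) {
  if (length(scores) != length(true_labels))
    stopf("scores and labels must have equal length")
  bad <- setdiff(unique(true_labels), c("normal", "abnormal"))
  if (length(bad))
    stopf("unknown label value(s): %s", paste(bad, collapse = ", "))
  pos <- true_labels == "abnormal"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stopf("AUC needs both classes present (got %d abnormal, %d normal)",
          n1, n0)
  r <- rank(scores)                      # midranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full evaluation report
#'
#' @param scores Numeric anomaly scores of the test beats.
#' @param true_labels `{"normal", "abnormal"}` per beat.
#' @param threshold Fitted threshold T for [classify_scores()].
#' @return A list of class `eval_report`: `counts`, `acc`, `pre`, `rec`,
#'   `f1`, `auc` (NA with a message in `notes` when only one class is
#'   present), `threshold`, `n`.
#' @export
evaluate_detector <- function(scores, true_labels, threshold) {
  pred <- classify_scores(scores, threshold)
  counts <- confusion(true_labels, pred)
  m <- metrics(counts)
  notes <- character(0)
  auc <- tryCatch(auc_score(scores, true_labels), error = function(e) {
    notes <<- c(notes, conditionMessage(e))
    NA_real_
  })
  structure(list(counts = counts, acc = m[["acc"]], pre = m[["pre"]],
                 rec = m[["rec"]], f1 = m[["f1"]], auc = auc,
                 threshold = threshold, n = sum(counts),
                 undefined = attr(m, "undefined"), notes = notes),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d (abnormal = positive)\n", x$n))
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d   threshold %.6g\n",
              x$counts[["TP"]], x$counts[["TN"]], x$counts[["FP"]],
              x$counts[["FN"]], x$threshold))
  cat(sprintf("  acc %.4f  pre %.4f  rec %.4f  f1 %.4f  auc %.4f\n",
              x$acc, x$pre, x$rec, x$f1, x$auc))
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
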