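# Threshold-free and thresholded classification metrics, confusion analysis,
# and primary-vs-subsequent fracture stratification.

#' Area under the ROC curve
#'
#' Computed with the rank (Mann-Whitney) formulation: the probability that a
#' randomly chosen positive outranks a randomly chosen negative, with ties
#' counted as half.
#'
#' @param probabilities numeric scores.
#' @param labels logical (or 0/1) labels; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(probabilities, labels) {
  labels <- as.logical(labels)
  stopifnot(length(probabilities) == length(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stopf("auroc is undefined with a single-class input (%d positives, %d negatives)",
          n_pos, n_neg)
  }
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Uses the average-precision formulation: step-wise integration of
#' precision over recall across descending score thresholds (no trapezoidal
#' interpolation). Tied scores are handled as a single threshold.
#'
#' @inheritParams auroc
#' @return average precision in \[0, 1\].
#' @export
auprc <- function(probabilities, labels) {
  labels <- as.logical(labels)
  stopifnot(length(probabilities) == length(labels))
  n_pos <- sum(labels)
  if (n_pos == 0L) stopf("auprc is undefined with no positive labels")
  ord <- order(probabilities, decreasing = TRUE)
  p <- probabilities[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  # last index of each tied-score block = one operating point per threshold
  n <- length(p)
  last <- if (n > 1L) c(which(p[-n] != p[-1L]), n) else n
  tp_t <- tp[last]
  fp_t <- fp[last]
  prec <- tp_t / (tp_t + fp_t)
  rec <- tp_t / n_pos
  d_rec <- diff(c(0, rec))
  sum(d_rec * prec)
}

#' Confusion counts at a decision threshold
#'
#' A row is flagged when its probability is greater than or equal to the
#' threshold.
#'
#' @inheritParams auroc
#' @param threshold decision threshold.
#' @return named integer vector `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_threshold <- function(probabilities, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  flag <- probabilities >= threshold
  c(tp = sum(flag & labels), fp = sum(flag & !labels),
    tn = sum(!flag & !labels), fn = sum(!flag & labels))
}

#' Evaluate predictions against labels
#'
#' Produces the standard report: AUROC, AUPRC, and the thresholded recall
#' (sensitivity), specificity and precision with their confusion counts.
#'
#' @inheritParams confusion_at_threshold
#' @param stratum label attached to the report (default `"overall"`).
#' @return an `evaluation_report`.
#' @export
evaluate <- function(probabilities, labels, threshold = 0.5,
                     stratum = "overall") {
  labels <- as.logical(labels)
  cm <- confusion_at_threshold(probabilities, labels, threshold)
  structure(list(
    auroc = auroc(probabilities, labels),
    auprc = auprc(probabilities, labels),
    recall = unname(cm["tp"] / (cm["tp"] + cm["fn"])),
    specificity = unname(cm["tn"] / (cm["tn"] + cm["fp"])),
    precision = unname(if (cm["tp"] + cm["fp"] == 0L) NA_real_
                       else cm["tp"] / (cm["tp"] + cm["fp"])),
    threshold = threshold, confusion = cm, n = length(labels),
    stratum = stratum),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat(sprintf("<evaluation_report> stratum %s (n = %d, threshold %.3g)\n",
              x$stratum, x$n, x$threshold))
  cat(sprintf("  AUROC %.*f | Recall %.*f | Specificity %.*f | Precision %s | AUPRC %.*f\n",
              digits, x$auroc, digits, x$recall, digits, x$specificity,
              ifelse(is.na(x$precision), "NA",
                     formatC(x$precision, digits = digits, format = "f")),
              digits, x$auprc))
  cm <- x$confusion
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", cm["tp"], cm["fp"], cm["tn"],
              cm["fn"]))
  invisible(x)
}

#' Evaluate overall and stratified by primary vs subsequent fracture
#'
#' Positive windows are assigned to the `primary` or `subsequent` stratum
#' from their anchor fracture's `is_subsequent` flag; negative windows are
#' type-free and join the negatives of both strata.
#'
#' @param predictions prediction table (`window_id`, `probability`).
#' @param windows windows table carrying `label` and `is_subsequent`.
#' @param threshold decision threshold.
#' @return list of `evaluation_report`s: `overall`, `primary`, `subsequent`
#'   (a stratum with no positives is reported as `NULL`).
#' @export
evaluate_stratified <- function(predictions, windows, threshold = 0.5) {
  x <- merge(windows[, .(window_id, label, is_subsequent)], predictions,
             by = "window_id")
  out <- list(overall = evaluate(x$probability, x$label, threshold, "overall"))
  for (st in c("primary", "subsequent")) {
    want_sub <- st == "subsequent"
    sel <- x[!label | is_subsequent == want_sub]
    out[[st]] <- if (sum(sel$label) > 0L && sum(!sel$label) > 0L) {
      evaluate(sel$probability, sel$label, threshold, st)
    } else {
      NULL
    }
  }
  out
}
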