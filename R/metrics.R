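# Classification metric panel: confusion matrix, per-class precision /
# recall / F1, macro and weighted averages, rank-statistic ROC-AUC.
# Arithmetic is kept in full precision; `round3()` mirrors the conventional
# 3-decimal reporting style only at presentation time.

#' Metric panel from confusion counts
#'
#' Exact arithmetic on the four confusion-matrix cells. Class 1 is the
#' positive (active) class. Undefined ratios (zero denominators) are
#' returned as `NaN` and flagged in `undefined`.
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return object of class `metric_panel`: confusion counts, per-class
#'   precision/recall/F1/support, accuracy, macro and weighted averages.
#' @export
metrics_from_confusion <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("input error: confusion counts must be non-negative integers",
         call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("input error: empty confusion matrix", call. = FALSE)
  div <- function(num, den) if (den == 0) NaN else num / den
  precision1 <- div(tp, tp + fp)
  recall1 <- div(tp, tp + fn)
  precision0 <- div(tn, tn + fn)
  recall0 <- div(tn, tn + fp)
  f1 <- function(p, r) if (is.nan(p) || is.nan(r) || p + r == 0) NaN else
    2 * p * r / (p + r)
  support1 <- tp + fn
  support0 <- tn + fp
  per_class <- data.frame(
    class = c(0, 1),
    precision = c(precision0, precision1),
    recall = c(recall0, recall1),
    f1 = c(f1(precision0, recall0), f1(precision1, recall1)),
    support = c(support0, support1))
  w <- per_class$support / n
  panel <- list(
    confusion = counts,
    per_class = per_class,
    accuracy = (tp + tn) / n,
    macro = c(precision = mean(per_class$precision),
              recall = mean(per_class$recall),
              f1 = mean(per_class$f1)),
    weighted = c(precision = sum(w * per_class$precision),
                 recall = sum(w * per_class$recall),
                 f1 = sum(w * per_class$f1)),
    support = n,
    undefined = names(which(vapply(
      list(precision1 = precision1, recall1 = recall1,
           precision0 = precision0, recall0 = recall0),
      is.nan, logical(1)))))
  class(panel) <- "metric_panel"
  panel
}

#' @export
print.metric_panel <- function(x, ...) {
  cat("Classification report (n =", x$support, ")\n")
  pc <- x$per_class
  pc[2:4] <- lapply(pc[2:4], round3)
  print(pc, row.names = FALSE)
  cat("accuracy:", round3(x$accuracy),
      " macro recall:", round3(x$macro["recall"]),
      " macro F1:", round3(x$macro["f1"]), "\n")
  if (!is.null(x$roc_auc)) cat("ROC-AUC:", round3(x$roc_auc), "\n")
  invisible(x)
}

#' Round to the conventional 3 reported decimals
#' @param x numeric.
#' @export
round3 <- function(x) round(x, 3)

#' Rank-statistic ROC-AUC
#'
#' AUC as the Wilcoxon-Mann-Whitney statistic: the probability that a
#' random active scores above a random inactive, with ties counted half
#' (midranks).
#'
#' @param scores numeric scores, larger = more active.
#' @param labels binary 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate probabilistic predictions against binary labels
#'
#' Hard predictions are `p >= threshold`; the panel of
#' [metrics_from_confusion()] is augmented with the rank-statistic ROC-AUC.
#' With single-class labels the threshold metrics are still returned and
#' `roc_auc` is `NA` (undefined).
#'
#' @param probabilities numeric vector in \[0, 1\].
#' @param labels binary 0/1 vector of the same length.
#' @param threshold classification threshold (default 0.5, the standard
#'   activity cutoff).
#' @return `metric_panel` with an extra `roc_auc` element.
#' @export
evaluate <- function(probabilities, labels, threshold = 0.5) {
  stopifnot(length(probabilities) == length(labels))
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE)) {
    stop("input error: probabilities outside [0, 1]", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("input error: labels must be binary", call. = FALSE)
  }
  pred <- as.integer(probabilities >= threshold)
  panel <- metrics_from_confusion(
    tp = sum(pred == 1 & labels == 1), fp = sum(pred == 1 & labels == 0),
    tn = sum(pred == 0 & labels == 0), fn = sum(pred == 0 & labels == 1))
  panel$threshold <- threshold
  panel$roc_auc <- if (length(unique(labels)) < 2) NA_real_ else
    roc_auc(probabilities, labels)
  panel
}

#' Histogram of prediction probabilities
#'
#' Bins the predicted probabilities and reports the two screening-relevant
#' mass fractions: high-confidence calls (p > 0.9) and ambiguous calls
#' (0.4 <= p <= 0.6).
#'
#' @param probabilities numeric vector in \[0, 1\].
#' @param bin_edges increasing break points spanning \[0, 1\]
#'   (default 10 equal bins).
#' @return list with `counts` (per bin, summing to `n`), `bin_edges`,
#'   `fraction_high_confidence` and `fraction_ambiguous`.
#' @export
probability_histogram <- function(probabilities, bin_edges = seq(0, 1, 0.1)) {
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("input error: probabilities outside [0, 1]", call. = FALSE)
  }
  counts <- as.integer(table(cut(probabilities, breaks = bin_edges,
                                 include.lowest = TRUE, right = TRUE)))
  list(counts = counts, bin_edges = bin_edges,
       n = length(probabilities),
       fraction_high_confidence = mean(probabilities > 0.9),
       fraction_ambiguous = mean(probabilities >= 0.4 & probabilities <= 0.6))
}
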