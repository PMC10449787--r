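#' Confusion counts for archaeal-virus calls
#'
#' Tallies true/false positives and negatives with the archaeal virus as
#' the positive class; phage and non-viral contaminant labels both count
#' as negatives.
#'
#' @param truth Character vector of true labels.
#' @param predicted Character vector of predicted labels (or logical:
#'   `TRUE` = archaeal call).
#' @return A one-row tibble `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted), length(truth) > 0)
  if (is.logical(predicted)) {
    predicted <- ifelse(predicted, av_positive_class, "phage")
  }
  pos_true <- truth == av_positive_class
  pos_pred <- predicted == av_positive_class
  tibble(TP = sum(pos_true & pos_pred), FP = sum(!pos_true & pos_pred),
         TN = sum(!pos_true & !pos_pred), FN = sum(pos_true & !pos_pred))
}

#' Confusion-derived performance metrics
#'
#' Computes the benchmarking metric set from confusion counts, at full
#' precision:
#' \deqn{TPR = TP/(TP+FN)\quad SPEC = TN/(TN+FP)\quad ACC = (TP+TN)/n}
#' \deqn{FDR = FP/(FP+TP)\quad
#'   MCC = (TP\,TN - FP\,FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' and F1 = 2TP/(2TP+FP+FN). Any metric with a zero denominator is
#' reported as `NA` rather than propagating NaN.
#'
#' @param counts A one-row tibble or named list with `TP`, `FP`, `TN`,
#'   `FN` (see [confusion_counts()]).
#' @return A one-row tibble `TPR`, `SPEC`, `ACC`, `MCC`, `FDR`, `F1`.
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  if (total == 0) abort("Confusion counts sum to zero")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) *
    sqrt((tn + fn))
  tibble(
    TPR = safe_div(tp, tp + fn),
    SPEC = safe_div(tn, tn + fp),
    ACC = (tp + tn) / total,
    MCC = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den,
    FDR = safe_div(fp, fp + tp),
    F1 = safe_div(2 * tp, 2 * tp + fp + fn)
  )
}

#' ROC and precision-recall curves with areas
#'
#' Builds both curves from per-contig archaeal probabilities and true
#' labels, sweeping the decision threshold over every distinct score (plus
#' the endpoints 0 and 1); rows scoring at or above a threshold are called
#' positive. Equal scores are grouped into a single threshold step. AUROC
#' is the trapezoid area over the (FPR, TPR) points, which equals the
#' concordant-pair rank statistic with ties counted 1/2; AUPRC is the
#' trapezoid area over the (recall, precision) points, anchored at
#' recall 0 with the precision of the most confident call.
#'
#' @param scores Tibble (or data frame) with columns `p_archaeal` and
#'   `label`, or a numeric vector of scores with `labels` supplied.
#' @param labels True labels when `scores` is a numeric vector.
#' @return An object of class `av_curve`: list with `points` (tibble
#'   `threshold`, `TP`, `FP`, `TPR`, `FPR`, `precision`), `auroc`,
#'   `auprc`, `n_pos`, `n_neg`.
#' @export
roc_pr <- function(scores, labels = NULL) {
  if (is.data.frame(scores)) {
    labels <- scores$label
    scores <- scores$p_archaeal
  }
  stopifnot(length(scores) == length(labels))
  pos <- labels == av_positive_class
  if (!any(pos) || all(pos)) {
    abort("Both classes must be present to build ROC/PR curves")
  }
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  thresholds <- sort(unique(c(0, 1, scores)), decreasing = TRUE)
  pts <- purrr::map_dfr(thresholds, function(t) {
    called <- scores >= t
    tp <- sum(called & pos)
    fp <- sum(called & !pos)
    tibble(threshold = t, TP = tp, FP = fp,
           TPR = tp / n_pos, FPR = fp / n_neg,
           precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp))
  })
  # anchor at the call-nothing origin: without it the initial segment is
  # lost whenever positives and negatives tie at the maximum score
  auroc <- trapezoid(c(0, pts$FPR), c(0, pts$TPR))
  pr <- pts[!is.na(pts$precision), , drop = FALSE]
  pr <- dplyr::bind_rows(tibble(threshold = Inf, TP = 0L, FP = 0L,
                                TPR = 0, FPR = 0,
                                precision = pr$precision[1]), pr)
  auprc <- trapezoid(pr$TPR, pr$precision)
  structure(list(points = pts, auroc = auroc, auprc = auprc,
                 n_pos = n_pos, n_neg = n_neg), class = "av_curve")
}

# Trapezoid rule in the given (threshold-descending) point order, along
# which x is non-decreasing; tied x collapse to zero-width segments.
trapezoid <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @export
print.av_curve <- function(x, ...) {
  cat("ROC / precision-recall curves over", nrow(x$points),
      "threshold steps\n")
  cat("  positives:", x$n_pos, " negatives:", x$n_neg, "\n")
  cat("  AUROC:", signif(x$auroc, 4), " AUPRC:", signif(x$auprc, 4), "\n")
  invisible(x)
}
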