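# Confusion-matrix construction and classification metrics, with the
# high-activity class as positive. Aggregation over repeats mirrors the
# benchmark summary layout (mean/SD/max of balanced accuracy and MCC per
# learner family and fold count).

#' Build a confusion matrix
#'
#' @param predicted,truth equal-length character vectors over
#'   `c("high", "low")`; `"high"` is the positive class.
#' @return object of class `odn_confusion`: list with integer `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    abort("confusion: prediction and truth lengths differ")
  }
  ok <- c("high", "low")
  if (!all(predicted %in% ok) || !all(truth %in% ok)) {
    abort("confusion: labels must be 'high' or 'low'")
  }
  structure(list(
    TP = sum(predicted == "high" & truth == "high"),
    TN = sum(predicted == "low" & truth == "low"),
    FP = sum(predicted == "high" & truth == "low"),
    FN = sum(predicted == "low" & truth == "high")
  ), class = "odn_confusion")
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), balanced accuracy =
#' (sensitivity + specificity)/2, Matthews correlation coefficient, and
#' precision = TP/(TP+FP). A metric whose denominator is zero is reported as
#' `NA` and named in the `undefined` attribute rather than silently coerced.
#'
#' @param cm an `odn_confusion` (or list with TP/TN/FP/FN).
#' @return object of class `odn_metrics`: named numeric vector
#'   `sensitivity`, `specificity`, `balanced_accuracy`, `mcc`, `precision`.
#' @export
classification_metrics <- function(cm) {
  tp <- as.numeric(cm$TP); tn <- as.numeric(cm$TN)
  fp <- as.numeric(cm$FP); fn <- as.numeric(cm$FN)
  if (tp + tn + fp + fn == 0) abort("classification_metrics: empty matrix")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  se <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  ba <- if (is.na(se) || is.na(sp)) NA_real_ else (se + sp) / 2
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_
  prec <- safe_div(tp, tp + fp)
  out <- c(sensitivity = se, specificity = sp, balanced_accuracy = ba,
           mcc = mcc, precision = prec)
  attr(out, "undefined") <- names(out)[is.na(out)]
  class(out) <- "odn_metrics"
  out
}

#' @export
print.odn_metrics <- function(x, ...) {
  cat(sprintf(
    "sensitivity %s  specificity %s  balanced accuracy %s  MCC %s  precision %s\n",
    format_percent(x[["sensitivity"]]), format_percent(x[["specificity"]]),
    format_percent(x[["balanced_accuracy"]]),
    sprintf("%.2f", round_half_up(x[["mcc"]], 2)),
    format_percent(x[["precision"]])
  ))
  if (length(attr(x, "undefined"))) {
    cat("undefined (zero denominator):",
        paste(attr(x, "undefined"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Aggregate per-repeat metrics into a benchmark summary
#'
#' @param results data.frame with columns `family`, `k`,
#'   `balanced_accuracy`, `mcc` (one row per repeat).
#' @return data.frame with one row per (family, k): mean, sample SD and
#'   maximum of balanced accuracy and MCC.
#' @export
aggregate_metrics <- function(results) {
  if (nrow(results) == 0L) abort("aggregate_metrics: no results")
  groups <- unique(results[, c("family", "k")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- results[results$family == groups$family[i] & results$k == groups$k[i], ]
    if (nrow(g) < 2L) abort("aggregate_metrics: group needs >= 2 repeats")
    data.frame(
      family = groups$family[i], k = groups$k[i], n_repeats = nrow(g),
      mean_ba = mean(g$balanced_accuracy), sd_ba = sd(g$balanced_accuracy),
      mean_mcc = mean(g$mcc), sd_mcc = sd(g$mcc),
      max_ba = max(g$balanced_accuracy), max_mcc = max(g$mcc)
    )
  }))
  rownames(out) <- NULL
  out
}
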