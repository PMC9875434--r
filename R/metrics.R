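#' Confusion counts for binary solubility predictions
#'
#' Soluble (label 1) is the positive class throughout the package.
#'
#' @param labels True 0/1 labels.
#' @param predictions Predicted 0/1 labels.
#' @return A `confusion_counts` list with integer fields `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion_counts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (any(!labels %in% 0:1) || any(!predictions %in% 0:1))
    stop("labels and predictions must be binary 0/1")
  out <- list(TP = sum(labels == 1L & predictions == 1L),
              TN = sum(labels == 0L & predictions == 0L),
              FP = sum(labels == 0L & predictions == 1L),
              FN = sum(labels == 1L & predictions == 0L))
  class(out) <- "confusion_counts"
  out
}

#' Threshold metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((FP+TP)(FN+TP)(FP+TN)(FN+TN))`, and the
#' balance statistic `|SN - SP| * 100` (percent). A zero MCC denominator
#' yields `MCC = 0` with `mcc_undefined = TRUE`; an absent class leaves SN
#' or SP as `NaN` (flagged via `one_class`). Values are stored at full
#' precision; the print method rounds to 4 decimals.
#'
#' @param counts A [confusion_counts()] object (or a list with TP/TN/FP/FN).
#' @param auc Optional AUC to carry into the report.
#' @param threshold Optional decision threshold to record.
#' @return An `evaluation_report` list with fields `ACC`, `SN`, `SP`,
#'   `MCC`, `balance`, `AUC`, `counts`, `threshold`, and flags.
#' @export
binary_metrics <- function(counts, auc = NA_real_, threshold = NA_real_) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total <= 0) stop("empty confusion counts")
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  den <- sqrt(fp + tp) * sqrt(fn + tp) * sqrt(fp + tn) * sqrt(fn + tn)
  mcc_undef <- den == 0
  mcc <- if (mcc_undef) 0 else (tp * tn - fp * fn) / den
  out <- list(ACC = (tp + tn) / total, SN = sn, SP = sp, MCC = mcc,
              balance = abs(sn - sp) * 100, AUC = auc,
              counts = counts, threshold = threshold,
              mcc_undefined = mcc_undef,
              one_class = is.nan(sn) || is.nan(sp))
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  ACC %.4f  SN %.4f  SP %.4f  |SN-SP|%% %.4f  MCC %.4f  AUC %s\n",
              x$ACC, x$SN, x$SP, x$balance, x$MCC,
              if (is.na(x$AUC)) "-" else sprintf("%.4f", x$AUC)))
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d%s\n",
              x$counts$TP, x$counts$TN, x$counts$FP, x$counts$FN,
              if (isTRUE(x$mcc_undefined)) "  [MCC undefined -> 0]" else ""))
  invisible(x)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over the distinct score values (ties
#' grouped), accumulating the true- and false-positive rates, and
#' integrates by trapezoid. Equivalent to the pairwise-concordance
#' (Mann-Whitney) statistic with ties counted 1/2.
#'
#' @param scores Numeric scores, larger = more soluble.
#' @param labels True 0/1 labels (1 = soluble = positive).
#' @return List with `auc` and a data frame `roc` of (`threshold`, `fpr`,
#'   `tpr`) points.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1L - y)
  last <- !duplicated(grp, fromLast = TRUE)   # last index of each tie group
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(auc = auc,
       roc = data.frame(threshold = c(Inf, s[last]), fpr = fpr, tpr = tpr))
}

#' Evaluate scored predictions against labels
#'
#' Convenience wrapper: thresholds scores, builds the confusion counts,
#' and returns the full report including AUC.
#'
#' @param scores Soluble-class probabilities or scores.
#' @param labels True 0/1 labels.
#' @param threshold Decision threshold (default 0.4, the ensemble's
#'   operating point).
#' @return An `evaluation_report`.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.4) {
  pred <- as.integer(scores >= threshold)
  binary_metrics(confusion_counts(labels, pred),
                 auc = roc_auc(scores, labels)$auc,
                 threshold = threshold)
}

#' Write an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(ACC = report$ACC, SN = report$SN, SP = report$SP,
         MCC = report$MCC, balance = report$balance, AUC = report$AUC,
         counts = report$counts[c("TP", "TN", "FP", "FN")],
         threshold = report$threshold),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
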