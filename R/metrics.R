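# Binary-classification metrics: confusion counts at a threshold plus the
# threshold-free AUROC by the rank (Mann-Whitney) formulation.

#' Compute classification metrics from labels and predicted probabilities
#'
#' Thresholding at `threshold` gives the confusion counts and from them
#' ACC = (TP+TN)/n, SN = TP/(TP+FN), SP = TN/(TN+FP), and Matthews'
#' correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)),
#' defined as 0 when the denominator vanishes.  AUROC is computed from ranks
#' (the Mann-Whitney statistic) with midrank tie handling, equivalent to the
#' fraction of (positive, negative) pairs ordered correctly counting ties as
#' one half.  AUROC needs both classes; with a single-class label vector it is
#' returned as `NA` with a warning while the other metrics are still computed.
#'
#' @param labels integer vector of 0/1 true labels (1 = active).
#' @param probs numeric vector of predicted probabilities, same length.
#' @param threshold decision threshold; predictions `>= threshold` count as
#'   positive.  The default 0.5 matches the sigmoid output's natural midpoint.
#' @return object of class `metrics_report`: list with `counts` (TP, FP, TN,
#'   FN), `ACC`, `SN`, `SP`, `MCC`, `AUROC`, `threshold`, `n`.
#' @examples
#' compute_metrics(c(1, 1, 1, 1, 0, 0, 0, 0),
#'                 c(0.9, 0.8, 0.7, 0.4, 0.6, 0.35, 0.2, 0.1))
#' @export
compute_metrics <- function(labels, probs, threshold = 0.5) {
  stopifnot(length(labels) == length(probs), all(labels %in% c(0, 1)))
  labels <- as.integer(labels)
  pred <- as.integer(probs >= threshold)
  TP <- sum(pred == 1L & labels == 1L); FP <- sum(pred == 1L & labels == 0L)
  TN <- sum(pred == 0L & labels == 0L); FN <- sum(pred == 0L & labels == 1L)
  n <- length(labels)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  structure(list(
    counts = c(TP = TP, FP = FP, TN = TN, FN = FN),
    ACC = (TP + TN) / n,
    SN = safe_div(TP, TP + FN),
    SP = safe_div(TN, TN + FP),
    MCC = if (mcc_den == 0) 0 else (TP * TN - FP * FN) / mcc_den,
    AUROC = auroc(labels, probs),
    threshold = threshold, n = n), class = "metrics_report")
}

#' Area under the ROC curve (rank formulation)
#'
#' @inheritParams compute_metrics
#' @return AUROC in `[0, 1]`, or `NA` (with a warning) when only one class is
#'   present.
#' @export
auroc <- function(labels, probs) {
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    warning("AUROC undefined: labels contain a single class", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(probs)  # midranks for ties
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat(sprintf("<metrics_report> n = %d, threshold = %g\n", x$n, x$threshold))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$counts["TP"], x$counts["FP"],
              x$counts["TN"], x$counts["FN"]))
  cat(sprintf("  ACC %.*f  SN %.*f  SP %.*f  MCC %.*f  AUROC %s\n",
              digits, x$ACC, digits, x$SN, digits, x$SP, digits, x$MCC,
              if (is.na(x$AUROC)) "NA" else formatC(x$AUROC, digits = digits,
                                                    format = "f")))
  invisible(x)
}

# mean +/- std strings like "0.893±0.006" used by the experiment tables
fmt_pm <- function(values, digits = 3) {
  sprintf("%.*f±%.*f", digits, mean(values), digits,
          if (length(values) > 1) stats::sd(values) else 0)
}

parse_pm <- function(s) as.numeric(strsplit(s, "±")[[1]])

# Aggregate per-fold metric reports into one mean +/- std row.
aggregate_metrics <- function(reports, digits = 3) {
  stopifnot(length(reports) >= 1)
  vals <- sapply(reports, function(r) c(ACC = r$ACC, SN = r$SN, SP = r$SP,
                                        MCC = r$MCC, AUROC = r$AUROC))
  means <- rowMeans(vals)
  sds <- apply(vals, 1, function(v) if (length(v) > 1) stats::sd(v) else 0)
  list(mean = means, sd = sds,
       formatted = stats::setNames(
         vapply(rownames(vals), function(m) fmt_pm(vals[m, ], digits),
                character(1)), rownames(vals)))
}
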