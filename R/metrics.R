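# Binary-classification evaluation: confusion at a threshold, ACC/SEN/SPE,
# and AUC via the Mann-Whitney rank statistic (ties counted one half).

#' Compute classification metrics
#'
#' Confusion counts at `threshold` on sigmoid scores (positives = label 1),
#' accuracy, sensitivity (true-positive rate), specificity (true-negative
#' rate) and rank-based AUC. With a single-class label vector the AUC is
#' undefined and returned as `NA` with a warning; the other metrics are still
#' computed.
#'
#' @param scores numeric scores in `[0, 1]` (probability of the positive
#'   class).
#' @param labels binary ground truth.
#' @param threshold decision threshold (default 0.5).
#' @return object of class `eval_report`: list with `acc`, `sen`, `spe`,
#'   `auc` and `confusion` (tp, fn, tn, fp).
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  check_binary_labels(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  auc <- if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined for a single-class label vector", call. = FALSE)
    NA_real_
  } else {
    r <- rank(scores)  # average ranks handle ties as 1/2
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  structure(list(
    acc = (tp + tn) / length(labels),
    sen = if (n1 > 0) tp / (tp + fn) else NA_real_,
    spe = if (n0 > 0) tn / (tn + fp) else NA_real_,
    auc = auc,
    confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
    threshold = threshold
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("ACC %.4f | SEN %s | SPE %s | AUC %s (threshold %.2f)\n",
              x$acc, fmt_or_na(x$sen), fmt_or_na(x$spe), fmt_or_na(x$auc),
              x$threshold))
  cat(sprintf("confusion: tp=%d fn=%d tn=%d fp=%d\n",
              x$confusion["tp"], x$confusion["fn"], x$confusion["tn"],
              x$confusion["fp"]))
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
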