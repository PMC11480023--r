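#' Binary classification metrics from probabilities
#'
#' Thresholds `y_prob` at `threshold`, tabulates the confusion counts and
#' returns accuracy, recall (sensitivity), specificity, precision, F1 and
#' the mean binary cross-entropy of the probabilities. A metric whose
#' denominator is zero is reported as 0 with a warning.
#'
#' @param y_true binary 0/1 truth vector
#' @param y_prob predicted probabilities in [0, 1]
#' @param threshold decision threshold (default 0.5)
#' @return one-row data.frame with columns `loss`, `accuracy`, `recall`,
#'   `specificity`, `precision`, `f1`, `tp`, `fp`, `tn`, `fn`
#' @export
compute_metrics <- function(y_true, y_prob, threshold = 0.5) {
  if (length(y_true) != length(y_prob)) {
    stop("`y_true` and `y_prob` must have equal length", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1))) {
    stop("`y_true` must be binary 0/1", call. = FALSE)
  }
  y_hat <- as.integer(y_prob >= threshold)
  tp <- sum(y_hat == 1 & y_true == 1)
  fp <- sum(y_hat == 1 & y_true == 0)
  tn <- sum(y_hat == 0 & y_true == 0)
  fn <- sum(y_hat == 0 & y_true == 1)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator): reported as 0", what))
      0
    } else num / den
  }
  acc <- (tp + tn) / length(y_true)
  rec <- safe_div(tp, tp + fn, "recall")
  spec <- safe_div(tn, tn + fp, "specificity")
  prec <- safe_div(tp, tp + fp, "precision")
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  p <- pmin(pmax(y_prob, 1e-7), 1 - 1e-7)
  loss <- -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
  data.frame(loss = loss, accuracy = acc, recall = rec, specificity = spec,
             precision = prec, f1 = f1, tp = tp, fp = fp, tn = tn, fn = fn)
}
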