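# ROC curve and AUC for single-substrate discrimination.

#' ROC curve and AUC for a two-class score
#'
#' AUC is computed by the Mann-Whitney identity: the probability that a
#' random positive-class score exceeds a random negative-class score, with
#' ties counting one half -- evaluated exactly via midranks. The curve is
#' built by thresholding at every distinct score (predicted positive when
#' `score >= threshold`), so its trapezoidal area equals the rank AUC
#' exactly, ties producing diagonal segments.
#'
#' @param scores Numeric scores (e.g. a substrate's activity rates).
#' @param labels Class labels, same length as `scores`.
#' @param positive_label The label treated as positive.
#' @return A `roc_result`: `auc`, `curve` (data frame `threshold`, `fpr`,
#'   `tpr`, starting at (0, 0) and ending at (1, 1)), `n_pos`, `n_neg`,
#'   `positive_label`.
#' @examples
#' r <- roc_curve_auc(c(4, 5, 6, 1, 2, 3), rep(c("UC", "CD"), each = 3), "UC")
#' r$auc  # 1: perfect separation
#' @export
roc_curve_auc <- function(scores, labels, positive_label) {
  scores <- as.numeric(scores)
  if (length(scores) != length(labels))
    abort_input("'scores' and 'labels' must have the same length")
  if (anyNA(scores) || any(is.infinite(scores)))
    abort_input("scores must be finite and non-missing")
  pos <- labels == positive_label
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos < 1L || n_neg < 1L)
    abort_input("need at least one observation in each class")
  # Mann-Whitney AUC via midranks (ties contribute 1/2).
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # Curve: one operating point per distinct threshold, descending.
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(s) sum(scores[pos] >= s), numeric(1))
  fp <- vapply(thr, function(s) sum(scores[!pos] >= s), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr),
                      fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg,
                 positive_label = positive_label),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (positive = %s; %d pos, %d neg, %d thresholds)\n",
              x$auc, x$positive_label, x$n_pos, x$n_neg, nrow(x$curve) - 1L))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr, type = "l", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}
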