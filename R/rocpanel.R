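# Diagnostic evaluation: ROC curves, Mann-Whitney AUC, Youden-index operating
# cutoffs and confusion summaries. Samples are called positive when their
# score is at or above the threshold (closed on the positive side).

check_labels <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop_fmt("scores and labels must align without missing values")
  }
  if (!any(labels) || all(labels)) stop_fmt("both classes must be present")
  labels
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive outscores a random negative, with ties
#' counted one half; computed from midranks.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (TRUE/1 = positive class).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- check_labels(scores, labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

roc_points <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  se <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, 0)
  sp <- vapply(thr, function(t) sum(scores < t & !labels) / n_neg, 0)
  data.frame(threshold = thr, sensitivity = se, specificity = sp)
}

#' Youden-index operating cutoff
#'
#' Exhaustive scan of the threshold grid (the unique scores) maximising
#' `J = sensitivity + specificity - 1`; ties break toward the smallest
#' cutoff. Positive call at `score >= cutoff`.
#'
#' @inheritParams auc
#' @return List: `cutoff`, `j`, `se`, `sp`, `confusion` (tp, fp, tn, fn) and
#'   false-call percentages of the total cohort.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- check_labels(scores, labels)
  grid <- sort(unique(scores))
  n_pos <- sum(labels); n_neg <- sum(!labels); n <- length(scores)
  # maximise J on an exact integer scale (tp * n_neg + tn * n_pos) so that
  # mathematical ties are true ties and break toward the smallest cutoff
  jnum <- vapply(grid, function(t) {
    sum(scores >= t & labels) * n_neg + sum(scores < t & !labels) * n_pos
  }, 0)
  j <- jnum / (n_pos * n_neg) - 1
  best <- grid[which.max(jnum)]  # which.max takes the first (smallest) maximiser
  tp <- sum(scores >= best & labels); fn <- n_pos - tp
  fp <- sum(scores >= best & !labels); tn <- n_neg - fp
  list(cutoff = best, j = max(j), se = tp / n_pos, sp = tn / n_neg,
       confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
       pct_false_pos = 100 * fp / n, pct_false_neg = 100 * fn / n)
}

#' ROC analysis of a score vector
#'
#' Builds the full ROC curve (thresholds = unique scores plus infinite
#' sentinels), the Mann-Whitney AUC, and the Youden operating point with its
#' confusion summary.
#'
#' @inheritParams auc
#' @return Object of class `roc_result` with elements `curve` (threshold,
#'   sensitivity, specificity), `auc`, `youden_cutoff`, `youden_j`,
#'   `se_at_cutoff`, `sp_at_cutoff`, `confusion`, `pct_false_pos`,
#'   `pct_false_neg`, `n_pos`, `n_neg`.
#' @examples
#' r <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' r$auc
#' @export
roc_analysis <- function(scores, labels) {
  labels <- check_labels(scores, labels)
  y <- youden_cutoff(scores, labels)
  structure(list(curve = roc_points(scores, labels),
                 auc = auc(scores, labels),
                 youden_cutoff = y$cutoff, youden_j = y$j,
                 se_at_cutoff = y$se, sp_at_cutoff = y$sp,
                 confusion = y$confusion,
                 pct_false_pos = y$pct_false_pos,
                 pct_false_neg = y$pct_false_neg,
                 n_pos = sum(labels), n_neg = sum(!labels)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC analysis: %d positives vs %d negatives\n", x$n_pos, x$n_neg))
  cat(sprintf("  AUC %.2f | cutoff %.4g | SE %.1f%% SP %.1f%% (J = %.3f)\n",
              x$auc, x$youden_cutoff, 100 * x$se_at_cutoff,
              100 * x$sp_at_cutoff, x$youden_j))
  cf <- x$confusion
  cat(sprintf("  confusion: tp %d fp %d tn %d fn %d | false pos %.1f%%, false neg %.1f%% of cohort\n",
              cf["tp"], cf["fp"], cf["tn"], cf["fn"],
              x$pct_false_pos, x$pct_false_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  with(x$curve, {
    graphics::plot(1 - specificity, sensitivity, type = "s",
                   xlab = "1 - specificity", ylab = "sensitivity",
                   xlim = c(0, 1), ylim = c(0, 1), ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  })
  graphics::points(1 - x$sp_at_cutoff, x$se_at_cutoff, pch = 19, col = "red")
  invisible(x)
}

# Trapezoidal area under the stored curve; used as an internal consistency
# check against the pair-counting AUC.
trapezoid_auc <- function(curve) {
  ord <- order(1 - curve$specificity, curve$sensitivity)
  x <- (1 - curve$specificity)[ord]
  y <- curve$sensitivity[ord]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}
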