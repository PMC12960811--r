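# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive implementation of the textbook
# definition, kept separate from the package's computational path.

# AUC by exhaustive pair counting, ties worth one half.
bf_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Youden maximiser by brute-force scan of every candidate threshold,
# smallest-cutoff tie break; positive call at score >= threshold.
bf_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  grid <- sort(unique(scores))
  best <- NULL
  for (t in grid) {
    se <- mean(scores[labels] >= t)
    sp <- mean(scores[!labels] < t)
    j <- se + sp - 1
    if (is.null(best) || j > best$j + 1e-15) best <- list(cutoff = t, j = j)
  }
  best
}

# Benjamini-Hochberg step-up, straight from the definition.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Two-sided Welch t-test via the Welch-Satterthwaite closed form.
bf_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(b) - mean(a)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

make_counts <- function(m, genes = NULL, samples = NULL, replicate_of = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  count_matrix(m, replicate_of = replicate_of)
}

make_meta <- function(sample_id, group, sex = "male", ...) {
  sample_table(data.frame(sample_id = sample_id, group = group, sex = sex,
                          ..., stringsAsFactors = FALSE))
}

# The 13-positive / 13-negative score fixture with exactly one
# misclassification per class at the Youden cutoff.
confusion_fixture <- function() {
  list(scores = c(rep(0.6, 12), 0.1, rep(0.2, 12), 0.7),
       labels = rep(c(TRUE, FALSE), each = 13))
}
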