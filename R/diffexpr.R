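# Discovery-stage statistics on the count matrix.
#
# Median-of-ratios normalisation, technical-replicate merging, sample QC,
# per-gene Welch tests on log-normalised counts with BH correction, and a PCA
# variance summary. This is a transparent stand-in for an NB-GLM differential
# pipeline: the discovery contract here is the downstream filter cascade, not
# equivalence with shrinkage-based DE machinery, so the test is a two-sided
# Welch t on log2(normalised counts + 1).

#' Median-of-ratios size factors
#'
#' Per gene, the reference is the geometric mean of its counts over samples
#' (genes with any zero are excluded from the reference set); the size factor
#' of a sample is the median over reference genes of `count / reference`.
#' Only factor ratios are identified: scaling one sample's depth by `k`
#' rescales every factor through the geometric-mean reference, leaving all
#' normalised profiles unchanged up to one common constant.
#'
#' @param counts A [count_matrix()] or numeric matrix.
#' @return Named vector of positive per-sample size factors.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  use <- rowSums(m == 0) == 0
  if (!any(use)) stop_fmt("no zero-free gene available for the reference")
  lm_ <- log(m[use, , drop = FALSE])
  ref <- rowMeans(lm_)
  sf <- apply(exp(lm_ - ref), 2, median)
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop_fmt("size factors are not all positive; check for empty samples")
  }
  sf
}

#' Normalised counts
#'
#' Divides each sample column by its median-of-ratios size factor.
#'
#' @param counts A [count_matrix()] or numeric matrix.
#' @param sf Optional precomputed size factors.
#' @return Numeric matrix of normalised counts.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (is.null(sf)) sf <- size_factors(m)
  sweep(m, 2, sf, "/")
}

#' Sum technical replicates into biological samples
#'
#' Replicate columns are summed into one column per biological sample, named
#' after the replicate parent. Without a replicate map this is the identity.
#'
#' @param counts A [count_matrix()].
#' @return A [count_matrix()] with one column per biological sample and no
#'   replicate map.
#' @export
merge_technical_replicates <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  map <- counts$replicate_of
  if (is.null(map) || !length(map)) return(counts)
  if (any(unname(map) %in% names(map))) {
    stop_fmt("replicate of a replicate is not allowed: %s",
             paste(intersect(unname(map), names(map)), collapse = ", "))
  }
  m <- counts$counts
  parent <- setNames(colnames(m), colnames(m))
  parent[names(map)] <- unname(map)
  groups <- split(seq_len(ncol(m)), parent[colnames(m)])
  merged <- vapply(groups, function(ix) rowSums(m[, ix, drop = FALSE]),
                   numeric(nrow(m)))
  if (nrow(m) == 1L) merged <- matrix(merged, nrow = 1L,
                                      dimnames = list(rownames(m), names(groups)))
  # keep original column order of the parents
  keep <- colnames(m)[!colnames(m) %in% names(map)]
  count_matrix(merged[, keep, drop = FALSE])
}

#' Sample quality control
#'
#' Drops samples whose total assigned counts fall below `min_assigned`, and
#' biological subjects whose technical replicates disagree: for each gene
#' expressed across a subject's replicates, the CV of `log2(count + 1)` is
#' taken across replicates, and the subject is dropped when the median CV
#' over expressed genes exceeds `max_replicate_cv`.
#'
#' @param counts A replicate-level [count_matrix()].
#' @param min_assigned Minimum total assigned reads per replicate column.
#' @param max_replicate_cv Maximum tolerated median log-scale replicate CV.
#' @return List with `kept` (sample ids) and `dropped` (data frame of sample
#'   id + reason). QC never raises on data content.
#' @export
sample_qc <- function(counts, min_assigned = 1e5, max_replicate_cv = 0.5) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  dropped <- data.frame(sample_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  totals <- colSums(m)
  low <- colnames(m)[totals < min_assigned]
  if (length(low)) {
    dropped <- rbind(dropped, data.frame(sample_id = low,
                                         reason = "low_assigned",
                                         stringsAsFactors = FALSE))
  }
  map <- counts$replicate_of
  if (!is.null(map) && length(map)) {
    parent <- setNames(colnames(m), colnames(m))
    parent[names(map)] <- unname(map)
    for (p in unique(unname(map))) {
      ix <- which(parent[colnames(m)] == p)
      if (length(ix) < 2L) next
      sub <- log2(m[, ix, drop = FALSE] + 1)
      expressed <- rowMeans(m[, ix, drop = FALSE]) >= 1
      if (!any(expressed)) next
      cv <- apply(sub[expressed, , drop = FALSE], 1,
                  function(v) if (mean(v) == 0) 0 else sd(v) / mean(v))
      if (median(cv) > max_replicate_cv) {
        dropped <- rbind(dropped, data.frame(sample_id = colnames(m)[ix],
                                             reason = "replicate_deviation",
                                             stringsAsFactors = FALSE))
      }
    }
  }
  dropped <- dropped[!duplicated(dropped$sample_id), , drop = FALSE]
  list(kept = setdiff(colnames(m), dropped$sample_id), dropped = dropped)
}

# Vectorised two-sided Welch t-test over matrix rows; returns t, df, p.
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  # degenerate rows (zero variance in both groups): no evidence either way
  flat <- !is.finite(t)
  t[flat] <- 0; p[flat] <- 1; df[flat] <- na + nb - 2
  data.frame(t_stat = t, df = df, p_value = p)
}

#' Per-gene differential test between two sample groups
#'
#' Computes base means of normalised counts (overall and per group), a
#' pseudocounted log2 fold change `log2((mean_B + c) / (mean_A + c))`, a
#' two-sided Welch t-test on `log2(normalised + c)`, BH-adjusted p-values
#' over all tested genes, and per-group outlier counts under the
#' geometric-mean separation rule of [count_outliers()].
#'
#' @param counts A [count_matrix()] (biological samples; merge replicates
#'   first).
#' @param meta A [sample_table()] covering the count columns.
#' @param groupA,groupB Functions of the metadata returning logical sample
#'   selectors, or character vectors of group labels (e.g. `"healthy"`).
#' @param pseudocount Pseudocount `c` on the normalised scale.
#' @return A data frame of class `de_result`: one row per gene with columns
#'   `gene`, `base_mean_all`, `base_mean_A`, `base_mean_B`, `log2fc`,
#'   `t_stat`, `df`, `p_value`, `p_adj`, `n_outliers_A`, `n_outliers_B`.
#' @export
de_test <- function(counts, meta, groupA = "healthy", groupB = "tumour",
                    pseudocount = 1) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop_fmt("metadata does not cover all count columns")
  selA <- if (is.function(groupA)) groupA(meta) else meta$group %in% groupA
  selB <- if (is.function(groupB)) groupB(meta) else meta$group %in% groupB
  if (sum(selA) < 2L || sum(selB) < 2L) {
    stop_fmt("each group needs >= 2 samples (A: %d, B: %d)", sum(selA), sum(selB))
  }
  norm <- normalize_counts(m)
  lg <- log2(norm + pseudocount)
  w <- welch_rows(lg[, selA, drop = FALSE], lg[, selB, drop = FALSE])
  meanA <- rowMeans(norm[, selA, drop = FALSE])
  meanB <- rowMeans(norm[, selB, drop = FALSE])
  grp <- rep(c("A", "B"), c(sum(selA), sum(selB)))
  out <- t(vapply(seq_len(nrow(norm)), function(i) {
    count_outliers(c(norm[i, selA], norm[i, selB]) + pseudocount, grp,
                   direction = if (meanB[i] >= meanA[i]) "up" else "down")
  }, numeric(2)))
  res <- data.frame(
    gene = rownames(m),
    base_mean_all = rowMeans(norm[, selA | selB, drop = FALSE]),
    base_mean_A = meanA, base_mean_B = meanB,
    log2fc = log2((meanB + pseudocount) / (meanA + pseudocount)),
    t_stat = w$t_stat, df = w$df, p_value = w$p_value,
    p_adj = p.adjust(w$p_value, method = "BH"),
    n_outliers_A = out[, 1], n_outliers_B = out[, 2],
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(res) <- c("de_result", "data.frame")
  res
}

#' PCA variance summary
#'
#' PCA of samples on gene-wise centred `log2(normalised counts + c)`; the
#' variance explained per component comes from the singular values.
#'
#' @param counts A [count_matrix()] or matrix with >= 2 samples.
#' @param pseudocount Pseudocount on the normalised scale.
#' @param scale. Scale genes to unit variance first (off by default, matching
#'   common RNA-seq QC practice).
#' @return List of class `pca_summary` with `variance_explained` (fractions,
#'   non-increasing, summing to <= 1) and the `prcomp` fit as `fit`.
#' @export
pca_summary <- function(counts, pseudocount = 1, scale. = FALSE) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (ncol(m) < 2L) stop_fmt("PCA needs >= 2 samples")
  lg <- t(log2(normalize_counts(m) + pseudocount))
  keep <- apply(lg, 2, function(v) stats::var(v) > 0)
  if (!any(keep)) {
    warning("constant matrix: no variance to decompose", call. = FALSE)
    ve <- rep(0, min(dim(lg)) - 1L)
    return(structure(list(variance_explained = ve, fit = NULL),
                     class = "pca_summary"))
  }
  fit <- prcomp(lg[, keep, drop = FALSE], center = TRUE,
                scale. = scale.)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(variance_explained = ve, fit = fit), class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  ve <- x$variance_explained
  cat("PCA variance explained:\n")
  for (i in seq_len(min(5L, length(ve)))) {
    cat(sprintf("  PC%d: %.1f%%\n", i, 100 * ve[i]))
  }
  invisible(x)
}
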