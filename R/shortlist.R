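# Candidate-selection logic: the robust largest-minimum fold change and the
# hard filter cascade that reduces significant genes to RT-qPCR candidates.

#' Robust (largest-minimum) fold change
#'
#' Worst-case separation ratio for a tumour-up candidate: the least-expressing
#' tumour sample over the highest-expressing healthy sample,
#' `min(tumour) / max(healthy)`. A value above 1 means every tumour sample
#' exceeds every healthy sample, so the difference is detectable in any
#' patient, not just on average — the property that makes a candidate robust
#' enough to carry over to RT-qPCR from a small sequencing cohort.
#'
#' @param healthy,tumour Non-empty vectors of normalised counts (apply a
#'   pseudocount upstream if zeros are possible).
#' @return A single positive ratio.
#' @examples
#' robust_fold_change(c(10, 20, 30), c(60, 80, 100))  # 2
#' @export
robust_fold_change <- function(healthy, tumour) {
  if (!length(healthy) || !length(tumour)) {
    stop_fmt("both group vectors must be non-empty")
  }
  if (any(healthy <= 0) || any(tumour <= 0)) {
    stop_fmt("values must be positive; apply a pseudocount upstream")
  }
  min(tumour) / max(healthy)
}

#' Genes significant and over-expressed in the pooled-healthy contrast
#'
#' Selects genes with `p_adj < alpha` and `log2fc > 0` (over-expressed in
#' tumour) in the all-healthy vs tumour contrast; optionally intersected with
#' the smoker and non-smoker contrasts.
#'
#' @param de_results A `de_result` (all-healthy contrast) or a named list of
#'   them; with `intersect = TRUE` the selection must hold in every listed
#'   contrast.
#' @param alpha Adjusted-significance level, strictly inside (0, 1).
#' @param intersect Require significance in every supplied contrast.
#' @return Character vector of gene ids.
#' @export
significant_in_all_contrasts <- function(de_results, alpha = 0.05,
                                         intersect = FALSE) {
  assert_scalar_in(alpha, "alpha", 0, 1, open = TRUE)
  if (inherits(de_results, "de_result")) de_results <- list(de_results)
  if (!length(de_results)) stop_fmt("'de_results' must be non-empty")
  sets <- lapply(de_results, function(de) {
    de$gene[de$p_adj < alpha & de$log2fc > 0]
  })
  if (intersect) Reduce(base::intersect, sets) else sets[[1]]
}

#' Count per-group outliers against a geometric-mean separation threshold
#'
#' The separation threshold `t*` is the geometric mean of the two group
#' medians. For an up-gene (group B elevated), a B sample below `t*` or an A
#' sample above `t*` counts as an outlier; for a down-gene the roles swap.
#'
#' @param values Positive values (normalised counts, pseudocounted upstream).
#' @param group_of Two-level labels aligned with `values`; the first level in
#'   sorted order is group A.
#' @param direction `"up"` if group B is the elevated one, else `"down"`.
#' @return Named numeric vector `c(n_outliers_A, n_outliers_B)`.
#' @export
count_outliers <- function(values, group_of, direction = c("up", "down")) {
  direction <- match.arg(direction)
  lev <- sort(unique(as.character(group_of)))
  if (length(lev) != 2L) stop_fmt("exactly two groups are required")
  a <- values[group_of == lev[1]]
  b <- values[group_of == lev[2]]
  if (!length(a) || !length(b)) stop_fmt("both groups must be non-empty")
  tstar <- sqrt(median(a) * median(b))
  hi_is_b <- direction == "up"
  hi <- if (hi_is_b) b else a
  lo <- if (hi_is_b) a else b
  n_hi <- sum(hi < tstar)  # elevated-group samples falling below separation
  n_lo <- sum(lo > tstar)  # baseline-group samples rising above it
  if (hi_is_b) c(n_outliers_A = n_lo, n_outliers_B = n_hi)
  else c(n_outliers_A = n_hi, n_outliers_B = n_lo)
}

#' Cascade thresholds
#'
#' Defaults follow the discovery filter: base mean > 25, log2FC > 2,
#' tumour-healthy base-mean difference within \[50, 3500\], and at most one
#' outlier per group.
#'
#' @param min_base_mean Strict lower bound on the overall base mean.
#' @param min_log2fc Strict lower bound on the log2 fold change.
#' @param min_diff,max_diff Inclusive window on `base_mean_B - base_mean_A`.
#' @param max_outliers_per_group Maximum tolerated outliers in each group.
#' @return List of class `cascade_config`.
#' @export
cascade_config <- function(min_base_mean = 25, min_log2fc = 2,
                           min_diff = 50, max_diff = 3500,
                           max_outliers_per_group = 1) {
  structure(list(min_base_mean = min_base_mean, min_log2fc = min_log2fc,
                 min_diff = min_diff, max_diff = max_diff,
                 max_outliers_per_group = max_outliers_per_group),
            class = "cascade_config")
}

#' Apply the candidate filter cascade
#'
#' Starting from the significant over-expressed candidates, applies in order:
#' overall base mean above `min_base_mean`; log2FC above `min_log2fc`;
#' per-group base-mean difference inside the `[min_diff, max_diff]` window;
#' and the outlier rule (at most `max_outliers_per_group` per group).
#' Survivors are ranked by robust fold change, descending.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param de A `de_result` for the healthy (A) vs tumour (B) contrast.
#' @param norm_counts Normalised count matrix (genes x samples).
#' @param meta A [sample_table()] covering the columns of `norm_counts`.
#' @param thresholds A [cascade_config()].
#' @param pseudocount Pseudocount applied before robust FC and outlier rules.
#' @return Data frame of class `shortlist`: per candidate gene, `robust_fc`,
#'   the five pass flags, `shortlisted`, and `rank` (NA for non-survivors).
#'   The funnel counts after each successive rule are attached as
#'   `attr(, "funnel")`.
#' @export
filter_cascade <- function(candidates, de, norm_counts, meta,
                           thresholds = cascade_config(), pseudocount = 1) {
  missing_de <- setdiff(candidates, de$gene)
  if (length(missing_de)) {
    stop_fmt("candidate gene(s) absent from DE results: %s",
             paste(missing_de, collapse = ", "))
  }
  missing_m <- setdiff(candidates, rownames(norm_counts))
  if (length(missing_m)) {
    stop_fmt("candidate gene(s) absent from count matrix: %s",
             paste(missing_m, collapse = ", "))
  }
  meta <- meta[match(colnames(norm_counts), meta$sample_id), , drop = FALSE]
  selH <- meta$group == "healthy"
  selT <- meta$group == "tumour"
  de <- de[match(candidates, de$gene), , drop = FALSE]

  flag_sig <- rep(TRUE, length(candidates))  # candidates come from the
                                             # significance selection
  flag_bm <- de$base_mean_all > thresholds$min_base_mean
  flag_fc <- de$log2fc > thresholds$min_log2fc
  diff <- de$base_mean_B - de$base_mean_A
  flag_diff <- diff >= thresholds$min_diff & diff <= thresholds$max_diff
  stats <- t(vapply(candidates, function(g) {
    h <- norm_counts[g, selH] + pseudocount
    tu <- norm_counts[g, selT] + pseudocount
    ou <- count_outliers(c(h, tu), rep(c("healthy", "tumour"),
                                       c(length(h), length(tu))),
                         direction = "up")
    c(robust_fc = robust_fold_change(h, tu), ou)
  }, numeric(3)))
  flag_out <- stats[, "n_outliers_A"] <= thresholds$max_outliers_per_group &
    stats[, "n_outliers_B"] <= thresholds$max_outliers_per_group

  res <- data.frame(
    gene = candidates,
    robust_fc = stats[, "robust_fc"],
    significant_all_healthy = flag_sig,
    base_mean_gt = flag_bm,
    log2fc_gt = flag_fc,
    diff_window = flag_diff,
    outlier_rule = flag_out,
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$shortlisted <- flag_sig & flag_bm & flag_fc & flag_diff & flag_out
  res$rank <- NA_integer_
  surv <- which(res$shortlisted)
  res$rank[surv[order(-res$robust_fc[surv])]] <- seq_along(surv)
  res <- res[order(is.na(res$rank), res$rank, -res$robust_fc), , drop = FALSE]
  row.names(res) <- NULL
  attr(res, "funnel") <- c(
    candidates = length(candidates),
    base_mean = sum(flag_sig & flag_bm),
    log2fc = sum(flag_sig & flag_bm & flag_fc),
    diff_window = sum(flag_sig & flag_bm & flag_fc & flag_diff),
    outlier_rule = sum(res$shortlisted)
  )
  class(res) <- c("shortlist", "data.frame")
  res
}
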