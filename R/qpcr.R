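# Validation-stage quantification: triplicate aggregation with QC, delta-Ct
# normalisation to the housekeeping gene, relative expression, group fold
# changes and Welch comparisons across the four cohort groups.

#' Aggregate replicate Ct values with quality control
#'
#' Per (sample, gene): mean and SD over non-missing replicates. When the SD
#' exceeds `max_sd` and `rescue` is on, the single replicate whose removal
#' minimises the SD is dropped; if the remaining pair's SD is within `max_sd`
#' the well is flagged `rescued`, otherwise `high_sd`. Fewer than two usable
#' replicates yield a `missing` flag and no value.
#'
#' @param ct A [ct_table()].
#' @param max_sd Maximum tolerated replicate SD (cycles).
#' @param rescue Attempt single-replicate rescue of noisy triplicates.
#' @return Data frame with one row per (sample, gene): `mean_ct`, `ct_sd`,
#'   `n_replicates`, `qc_flag` in `{ok, rescued, high_sd, missing}`.
#' @export
aggregate_triplicates <- function(ct, max_sd = 0.5, rescue = TRUE) {
  stopifnot(inherits(ct, "ct_table"))
  key <- interaction(ct$sample_id, ct$gene, drop = TRUE, lex.order = TRUE)
  pieces <- split(ct, key)
  rows <- lapply(pieces, function(d) {
    v <- d$ct[!is.na(d$ct)]
    base <- data.frame(sample_id = d$sample_id[1], gene = d$gene[1],
                       stringsAsFactors = FALSE)
    if (length(v) < 2L) {
      return(cbind(base, mean_ct = NA_real_, ct_sd = NA_real_,
                   n_replicates = length(v), qc_flag = "missing"))
    }
    m <- mean(v); s <- sd(v); flag <- "ok"; n <- length(v)
    if (s > max_sd) {
      if (rescue && length(v) >= 3L) {
        sds <- vapply(seq_along(v), function(i) sd(v[-i]), 0)
        i <- which.min(sds)
        if (sds[i] <= max_sd) {
          v2 <- v[-i]
          m <- mean(v2); s <- sds[i]; n <- length(v2); flag <- "rescued"
        } else flag <- "high_sd"
      } else flag <- "high_sd"
    }
    cbind(base, mean_ct = m, ct_sd = s, n_replicates = n, qc_flag = flag)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Delta-Ct of a target against the housekeeping gene
#'
#' `delta_ct = target - housekeeping`; relative expression is `2^-delta_ct`.
#'
#' @param target_mean_ct,housekeeping_mean_ct Aggregated mean Ct values.
#' @return The delta-Ct value.
#' @examples
#' delta_ct(25, 20)          # 5
#' 2^-delta_ct(25, 20)       # 0.03125
#' @export
delta_ct <- function(target_mean_ct, housekeeping_mean_ct) {
  target_mean_ct - housekeeping_mean_ct
}

#' Relative expression table from a Ct table
#'
#' Aggregates replicates, normalises each target against the sample's
#' housekeeping gene, and reports relative expression `2^-delta_ct` with QC
#' flags. Samples whose housekeeping well failed QC are flagged
#' `missing_housekeeping` and carry no expression values.
#'
#' @param ct A [ct_table()] including the housekeeping gene.
#' @param housekeeping Housekeeping gene name.
#' @param max_sd,rescue Passed to [aggregate_triplicates()].
#' @return Data frame of class `expression_table`: per (sample, target gene)
#'   `mean_ct`, `ct_sd`, `delta_ct`, `rel_expr`, `log2_rel_expr`, `qc_flag`.
#' @export
relative_expression <- function(ct, housekeeping = "MT-ATP6", max_sd = 0.5,
                                rescue = TRUE) {
  agg <- aggregate_triplicates(ct, max_sd = max_sd, rescue = rescue)
  if (!housekeeping %in% agg$gene) {
    stop_fmt("housekeeping gene '%s' absent from the Ct table", housekeeping)
  }
  hk <- agg[agg$gene == housekeeping, , drop = FALSE]
  hk_ct <- setNames(ifelse(hk$qc_flag %in% c("ok", "rescued"),
                           hk$mean_ct, NA_real_), hk$sample_id)
  tgt <- agg[agg$gene != housekeeping, , drop = FALSE]
  hk_for <- hk_ct[tgt$sample_id]
  dct <- delta_ct(tgt$mean_ct, hk_for)
  usable <- tgt$qc_flag %in% c("ok", "rescued") & !is.na(hk_for)
  tgt$qc_flag[tgt$qc_flag %in% c("ok", "rescued") & is.na(hk_for)] <-
    "missing_housekeeping"
  tgt$delta_ct <- ifelse(usable, dct, NA_real_)
  tgt$rel_expr <- 2^(-tgt$delta_ct)
  tgt$log2_rel_expr <- -tgt$delta_ct
  row.names(tgt) <- NULL
  class(tgt) <- c("expression_table", "data.frame")
  tgt
}

welch_log2 <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop_fmt("each group needs >= 2 usable samples (got %d and %d)",
             length(a), length(b))
  }
  degenerate <- function() {
    # essentially-constant data: no within-group spread to test against
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      list(t_stat = 0, df = length(a) + length(b) - 2, p_value = 1)
    } else {
      list(t_stat = sign(mean(b) - mean(a)) * Inf,
           df = length(a) + length(b) - 2, p_value = 0)
    }
  }
  out <- tryCatch({
    ht <- t.test(b, a, var.equal = FALSE)
    list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
  }, error = function(e) degenerate())
  # both groups constant: t.test returns 0/0 rather than raising
  if (!is.finite(out$t_stat) && !is.nan(out$t_stat)) return(out)
  if (is.nan(out$t_stat)) out <- degenerate()
  out
}

#' Group fold change and Welch comparison for one gene
#'
#' Fold change is the ratio of mean relative expression (`group_b` over
#' `group_a`, linear scale); the significance test is a two-sided Welch t on
#' `log2_rel_expr`.
#'
#' @param expr An `expression_table` from [relative_expression()].
#' @param meta A [sample_table()].
#' @param gene Target gene.
#' @param group_a,group_b Group labels (see [sample_table()] enums).
#' @return One-row data frame: `gene`, `group_a`, `group_b`, `n_a`, `n_b`,
#'   `mean_log2_a`, `mean_log2_b`, `fold_change`, `t_stat`, `df`, `p_value`.
#' @export
group_fold_change <- function(expr, meta, gene, group_a = "healthy",
                              group_b = "tumour") {
  bad <- setdiff(c(group_a, group_b), GROUP_LEVELS)
  if (length(bad)) stop_fmt("unknown group(s): %s", paste(bad, collapse = ", "))
  grp <- setNames(meta$group, meta$sample_id)
  d <- expr[expr$gene == gene & !is.na(expr$rel_expr), , drop = FALSE]
  a <- d[grp[d$sample_id] %in% group_a, , drop = FALSE]
  b <- d[grp[d$sample_id] %in% group_b, , drop = FALSE]
  w <- welch_log2(a$log2_rel_expr, b$log2_rel_expr)
  data.frame(gene = gene, group_a = group_a, group_b = group_b,
             n_a = nrow(a), n_b = nrow(b),
             mean_log2_a = mean(a$log2_rel_expr),
             mean_log2_b = mean(b$log2_rel_expr),
             fold_change = mean(b$rel_expr) / mean(a$rel_expr),
             t_stat = w$t_stat, df = w$df, p_value = w$p_value,
             stringsAsFactors = FALSE)
}

sig_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Per-marker group comparisons across cohort contrasts
#'
#' Runs [group_fold_change()] for each gene and contrast (default: tumour vs
#' healthy, tumour vs high-risk, tumour vs post-therapy, post-therapy vs
#' high-risk), with significance stars at 0.05 / 0.01.
#'
#' @param expr An `expression_table`.
#' @param meta A [sample_table()].
#' @param genes Target genes; empty input yields an empty table.
#' @param contrasts List of `c(group_a, group_b)` pairs.
#' @return Data frame with one row per gene x contrast.
#' @export
cohort_marker_stats <- function(expr, meta, genes,
                                contrasts = list(c("healthy", "tumour"),
                                                 c("high_risk", "tumour"),
                                                 c("post_therapy", "tumour"),
                                                 c("high_risk", "post_therapy"))) {
  rows <- list()
  for (g in genes) {
    for (ctr in contrasts) {
      rows[[length(rows) + 1L]] <-
        group_fold_change(expr, meta, g, group_a = ctr[1], group_b = ctr[2])
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(0), group_a = character(0),
                      group_b = character(0), n_a = integer(0),
                      n_b = integer(0), mean_log2_a = numeric(0),
                      mean_log2_b = numeric(0), fold_change = numeric(0),
                      t_stat = numeric(0), df = numeric(0),
                      p_value = numeric(0), signif = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$signif <- sig_stars(out$p_value)
  row.names(out) <- NULL
  out
}
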