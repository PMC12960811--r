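# Marker panels: a combined diagnostic score over several markers, fitted as
# an L2-penalised logistic model (mirroring GLM-based panel combination, so
# the operating cutoff lives on a probability scale) or as a transparent
# mean of per-marker z-scores. Evaluation is in-sample, as is usual for
# pilot-scale panel reports; no multiplicity correction is applied across
# combinations.

#' Pivot an expression table to a sample x gene matrix
#'
#' @param expr An `expression_table` from [relative_expression()].
#' @param genes Genes to keep (default: all).
#' @param value Column to pivot (default `log2_rel_expr`).
#' @return Numeric matrix, samples in rows, genes in columns; wells without a
#'   usable value are NA.
#' @export
expression_matrix <- function(expr, genes = NULL, value = "log2_rel_expr") {
  if (is.null(genes)) genes <- unique(expr$gene)
  samples <- unique(expr$sample_id)
  m <- matrix(NA_real_, length(samples), length(genes),
              dimnames = list(samples, genes))
  d <- expr[expr$gene %in% genes, , drop = FALSE]
  m[cbind(match(d$sample_id, samples), match(d$gene, genes))] <- d[[value]]
  m
}

#' Fit a diagnostic marker panel
#'
#' Standardises each marker's values, then combines them into one per-sample
#' score: `method = "logistic"` fits an L2-penalised (ridge) logistic model
#' of the class label on the standardised markers and scores each sample by
#' its in-sample predicted probability; `method = "mean_z"` takes the mean of
#' the per-marker z-scores. Constant markers are dropped with a warning. The
#' fitted object carries the full ROC analysis of its scores, including the
#' Youden operating cutoff.
#'
#' @param x Numeric matrix of marker values (samples x markers), typically
#'   log2 relative expression from [expression_matrix()].
#' @param labels Binary labels (TRUE/1 = positive class, e.g. tumour).
#' @param markers Markers (columns of `x`) to combine; duplicates are
#'   collapsed. Default: all columns.
#' @param method Combination rule.
#' @param ridge L2 penalty for the logistic combination; the small default
#'   stabilises the fit under separation while leaving probabilities close to
#'   the unpenalised model.
#' @return Object of class `marker_panel` with elements `markers`, `dropped`,
#'   `method`, `ridge`, `center`, `scale`, `coefficients`, `scores`,
#'   `labels`, and `roc` (a `roc_result`).
#' @examples
#' set.seed(1)
#' x <- cbind(m1 = c(rnorm(10), rnorm(10, 3)), m2 = rnorm(20))
#' fit <- marker_panel(x, rep(c(0, 1), each = 10))
#' fit$roc$auc
#' @export
marker_panel <- function(x, labels, markers = colnames(x),
                         method = c("logistic", "mean_z"), ridge = 1e-6) {
  method <- match.arg(method)
  markers <- unique(markers)
  if (!all(markers %in% colnames(x))) {
    stop_fmt("marker(s) absent from 'x': %s",
             paste(setdiff(markers, colnames(x)), collapse = ", "))
  }
  keep <- stats::complete.cases(x[, markers, drop = FALSE]) & !is.na(labels)
  xm <- x[keep, markers, drop = FALSE]
  labels <- check_labels(rowMeans(xm), as.logical(labels)[keep])
  ctr <- colMeans(xm)
  scl <- apply(xm, 2, sd)
  degenerate <- !is.finite(scl) | scl == 0
  if (any(degenerate)) {
    warn_fmt("dropping constant marker(s): %s",
             paste(markers[degenerate], collapse = ", "))
  }
  if (all(degenerate)) stop_fmt("all markers are constant")
  markers_used <- markers[!degenerate]
  z <- scale(xm[, markers_used, drop = FALSE], center = ctr[!degenerate],
             scale = scl[!degenerate])

  if (method == "logistic") {
    zz <- if (ncol(z) == 1L) cbind(z, `.pad` = 0) else z
    # pilot-scale class sizes are expected here; muffle glmnet's small-n note
    fit <- withCallingHandlers(
      glmnet::glmnet(zz, as.numeric(labels), family = "binomial",
                     alpha = 0, lambda = ridge, standardize = FALSE,
                     thresh = 1e-12),
      warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    scores <- as.numeric(stats::predict(fit, newx = zz, type = "response"))
    beta <- as.numeric(fit$beta)[seq_along(markers_used)]
    coefs <- c(`(Intercept)` = as.numeric(fit$a0),
               setNames(beta, markers_used))
  } else {
    scores <- rowMeans(z)
    coefs <- setNames(rep(1 / ncol(z), ncol(z)), markers_used)
  }
  names(scores) <- rownames(xm)
  structure(list(markers = markers_used, dropped = markers[degenerate],
                 method = method, ridge = ridge,
                 center = ctr[!degenerate], scale = scl[!degenerate],
                 coefficients = coefs, scores = scores, labels = labels,
                 roc = roc_analysis(scores, labels)),
            class = "marker_panel")
}

#' Per-sample combined panel score
#'
#' Functional wrapper around [marker_panel()] returning only the scores.
#'
#' @inheritParams marker_panel
#' @return Named numeric vector of per-sample scores (predicted probability
#'   for `"logistic"`, mean z-score for `"mean_z"`).
#' @export
combo_score <- function(x, labels, markers = colnames(x),
                        method = c("logistic", "mean_z"), ridge = 1e-6) {
  if (length(unique(markers)) < 2L) stop_fmt("a combination needs >= 2 markers")
  marker_panel(x, labels, markers, method = method, ridge = ridge)$scores
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel (%s): %s\n", x$method,
              paste(x$markers, collapse = " + ")))
  if (length(x$dropped)) {
    cat(sprintf("  dropped constant: %s\n", paste(x$dropped, collapse = ", ")))
  }
  cat(sprintf("  AUC %.2f | cutoff %.4g | SE %.1f%% SP %.1f%%\n",
              x$roc$auc, x$roc$youden_cutoff, 100 * x$roc$se_at_cutoff,
              100 * x$roc$sp_at_cutoff))
  invisible(x)
}

#' @export
summary.marker_panel <- function(object, ...) {
  print(object)
  cat("  coefficients (standardised scale):\n")
  for (nm in names(object$coefficients)) {
    cat(sprintf("    %-14s % .4f\n", nm, object$coefficients[[nm]]))
  }
  print(object$roc)
  invisible(object)
}

#' @export
coef.marker_panel <- function(object, ...) object$coefficients

#' Predict panel scores or classes for new samples
#'
#' @param object A fitted [marker_panel()].
#' @param newdata Matrix with the panel's marker columns (raw scale, as
#'   fitted); default: the training data scores.
#' @param type `"score"` for the combined score, `"class"` for the positive /
#'   negative call at the fitted Youden cutoff.
#' @param ... Unused.
#' @export
predict.marker_panel <- function(object, newdata = NULL,
                                 type = c("score", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    s <- object$scores
  } else {
    z <- scale(newdata[, object$markers, drop = FALSE],
               center = object$center, scale = object$scale)
    if (object$method == "logistic") {
      co <- object$coefficients
      eta <- co[["(Intercept)"]] +
        as.numeric(z %*% co[object$markers])
      s <- 1 / (1 + exp(-eta))
    } else {
      s <- rowMeans(z)
    }
    names(s) <- rownames(newdata)
  }
  if (type == "score") s else s >= object$roc$youden_cutoff
}

#' @export
plot.marker_panel <- function(x, ...) {
  plot(x$roc, main = paste(x$markers, collapse = " + "), ...)
}

#' @export
residuals.marker_panel <- function(object, ...) {
  as.numeric(object$labels) - object$scores
}

#' Evaluate every marker combination
#'
#' Enumerates all subsets of the markers with sizes in
#' `[min_size, max_size]`, fits a [marker_panel()] for each, and ranks the
#' combinations by AUC (descending), then Youden J, then smaller panel size.
#' Four markers at sizes 2-4 give the classic 6 + 4 + 1 = 11 combinations.
#'
#' @inheritParams marker_panel
#' @param min_size,max_size Subset size range; `min_size` must be >= 2
#'   (single markers go through [roc_analysis()] directly).
#' @return Data frame of class `combo_eval`: per combination `combo`,
#'   `size`, `auc`, `youden_cutoff`, `youden_j`, `se`, `sp`, `tp`, `fp`,
#'   `tn`, `fn`, `rank`.
#' @export
evaluate_combos <- function(x, labels, markers = colnames(x), min_size = 2,
                            max_size = length(unique(markers)),
                            method = c("logistic", "mean_z"), ridge = 1e-6) {
  method <- match.arg(method)
  markers <- unique(markers)
  if (min_size < 2) stop_fmt("min_size must be >= 2")
  if (max_size > length(markers)) {
    stop_fmt("max_size exceeds the number of distinct markers")
  }
  rows <- list()
  for (k in seq(min_size, max_size)) {
    for (combo in utils::combn(markers, k, simplify = FALSE)) {
      fit <- marker_panel(x, labels, combo, method = method, ridge = ridge)
      r <- fit$roc
      rows[[length(rows) + 1L]] <- data.frame(
        combo = paste(combo, collapse = "+"), size = k, auc = r$auc,
        youden_cutoff = r$youden_cutoff, youden_j = r$youden_j,
        se = r$se_at_cutoff, sp = r$sp_at_cutoff,
        tp = r$confusion[["tp"]], fp = r$confusion[["fp"]],
        tn = r$confusion[["tn"]], fn = r$confusion[["fn"]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$auc, -out$youden_j, out$size)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  row.names(out) <- NULL
  class(out) <- c("combo_eval", "data.frame")
  out
}

#' Single-marker and panel metrics per cohort stratum
#'
#' Re-runs the single-marker ROC analyses and the combination enumeration
#' independently within each stratum (e.g. sex), then reports cross-stratum
#' AUC differences. Strata with fewer than two samples in either class are
#' skipped with a warning.
#'
#' @inheritParams evaluate_combos
#' @param strata Character vector of stratum labels aligned with the rows of
#'   `x`.
#' @return Data frame with one row per stratum x marker set (`type` single or
#'   combo), with the cross-stratum AUC difference table attached as
#'   `attr(, "auc_differences")`.
#' @export
stratified_eval <- function(x, labels, strata, markers = colnames(x),
                            min_size = 2,
                            max_size = length(unique(markers)),
                            method = c("logistic", "mean_z"), ridge = 1e-6) {
  method <- match.arg(method)
  labels <- as.logical(labels)
  rows <- list()
  for (s in unique(strata)) {
    sel <- strata == s & !is.na(labels)
    ok <- stats::complete.cases(x[, unique(markers), drop = FALSE]) & sel
    if (sum(labels[ok]) < 2L || sum(!labels[ok]) < 2L) {
      warn_fmt("stratum '%s' lacks two samples per class; skipped", s)
      next
    }
    xs <- x[ok, , drop = FALSE]; ls <- labels[ok]
    for (m in unique(markers)) {
      r <- roc_analysis(xs[, m], ls)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, combo = m, type = "single", auc = r$auc,
        youden_cutoff = r$youden_cutoff, se = r$se_at_cutoff,
        sp = r$sp_at_cutoff, stringsAsFactors = FALSE)
    }
    ce <- evaluate_combos(xs, ls, markers, min_size = min_size,
                          max_size = max_size, method = method, ridge = ridge)
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = s, combo = ce$combo, type = "combo", auc = ce$auc,
      youden_cutoff = ce$youden_cutoff, se = ce$se, sp = ce$sp,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop_fmt("no stratum was evaluable")
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  strata_seen <- unique(out$stratum)
  if (length(strata_seen) >= 2L) {
    wide <- tapply(out$auc, list(out$combo, out$stratum), identity)
    diffs <- utils::combn(strata_seen, 2, function(p) {
      data.frame(combo = rownames(wide), stratum_a = p[1], stratum_b = p[2],
                 auc_diff = wide[, p[1]] - wide[, p[2]],
                 stringsAsFactors = FALSE, row.names = NULL)
    }, simplify = FALSE)
    attr(out, "auc_differences") <- do.call(rbind, diffs)
  }
  out
}
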