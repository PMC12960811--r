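# Orchestration: configuration, the simulate -> discover -> qpcr -> roc ->
# combi workflow, artifact writing and report generation. All randomness
# flows from the config seed; a rerun with the same config is byte-identical.

#' Pipeline configuration
#'
#' Flat, human-editable key-value configuration covering every stage
#' threshold. Defaults are the study defaults (cascade 25 / 2 / \[50, 3500\] /
#' <= 1 outlier, alpha 0.05, triplicate SD 0.5 with rescue, ridge 1e-6,
#' combination sizes 2-4).
#'
#' @param seed Master seed.
#' @param n_genes,n_marker_genes,n_smoking_genes Simulated gene panel sizes.
#' @param marker_log2fc,smoking_log2fc,female_effect_attenuation Planted
#'   effect sizes.
#' @param alpha Adjusted-significance level for candidate selection.
#' @param min_base_mean,min_log2fc,min_diff,max_diff,max_outliers Cascade
#'   thresholds (see [cascade_config()]).
#' @param pseudocount Pseudocount on the normalised count scale.
#' @param min_assigned,max_replicate_cv Sample QC thresholds.
#' @param housekeeping Housekeeping gene name.
#' @param max_sd,rescue Triplicate QC (see [aggregate_triplicates()]).
#' @param method,ridge,combo_min_size,combo_max_size Panel combination
#'   settings.
#' @return List of class `run_config` (schema version attached).
#' @export
run_config <- function(seed = 1L, n_genes = 2000L, n_marker_genes = 40L,
                       n_smoking_genes = 40L, marker_log2fc = 3,
                       smoking_log2fc = 2, female_effect_attenuation = 0.3,
                       alpha = 0.05, min_base_mean = 25, min_log2fc = 2,
                       min_diff = 50, max_diff = 3500, max_outliers = 1,
                       pseudocount = 1, min_assigned = 1000,
                       max_replicate_cv = 0.5, housekeeping = "MT-ATP6",
                       max_sd = 0.5, rescue = TRUE,
                       method = "logistic", ridge = 1e-6,
                       combo_min_size = 2L, combo_max_size = 4L) {
  cfg <- list(schema = 1L, seed = as.integer(seed), n_genes = n_genes,
              n_marker_genes = n_marker_genes,
              n_smoking_genes = n_smoking_genes,
              marker_log2fc = marker_log2fc, smoking_log2fc = smoking_log2fc,
              female_effect_attenuation = female_effect_attenuation,
              alpha = alpha, min_base_mean = min_base_mean,
              min_log2fc = min_log2fc, min_diff = min_diff,
              max_diff = max_diff, max_outliers = max_outliers,
              pseudocount = pseudocount, min_assigned = min_assigned,
              max_replicate_cv = max_replicate_cv,
              housekeeping = housekeeping, max_sd = max_sd, rescue = rescue,
              method = method, ridge = ridge,
              combo_min_size = combo_min_size,
              combo_max_size = combo_max_size)
  class(cfg) <- "run_config"
  cfg
}

#' Write a configuration as flat key=value text
#' @param config A [run_config()].
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(v) {
    if (is.character(v)) v else format(v, digits = 17)
  }, "")
  writeLines(paste(names(config), vals, sep = "="), path)
  invisible(path)
}

#' Read a configuration written by [write_config()]
#'
#' Types are restored from the default schema; the round trip is lossless.
#'
#' @param path Path to the key=value file.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  defaults <- run_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) {
    stop_fmt("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  for (i in seq_along(keys)) {
    k <- keys[i]
    cfg[[k]] <- switch(class(defaults[[k]])[1],
                       integer = as.integer(vals[i]),
                       numeric = as.numeric(vals[i]),
                       logical = as.logical(vals[i]),
                       vals[i])
  }
  class(cfg) <- "run_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_fmt("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full synthetic-cohort workflow
#'
#' Executes simulate -> discover (QC, replicate merge, DE contrasts,
#' candidate selection, filter cascade) -> qpcr (delta-Ct expression, group
#' comparisons) -> roc (single markers) -> combi (panel enumeration,
#' sex-stratified re-analysis), writing every artifact (TSV/CSV/JSON plus
#' report.md) under `out_dir`. Deterministic given `config$seed`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress INFO logging of the discovery funnel.
#' @return Invisibly, a list of class `run_report` with the funnel counts,
#'   per-marker stats, combo and stratified tables, and provenance.
#' @export
run_all <- function(config = run_config(), out_dir = tempfile("swabmark_"),
                    quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  info <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  design <- sim_design(seed = config$seed, n_genes = config$n_genes,
                       n_marker_genes = config$n_marker_genes,
                       n_smoking_genes = config$n_smoking_genes)
  params <- sim_params(marker_log2fc = config$marker_log2fc,
                       smoking_log2fc = config$smoking_log2fc,
                       female_effect_attenuation = config$female_effect_attenuation,
                       housekeeping_gene = config$housekeeping)

  sim <- stage("simulate", {
    s <- simulate_counts(design, params)
    v <- simulate_ct(design, params, s$truth)
    write_counts(s$counts, file.path(out_dir, "counts.tsv"))
    write_metadata(s$meta, file.path(out_dir, "meta_discovery.csv"))
    write_ct(v$ct, file.path(out_dir, "ct.csv"))
    write_metadata(v$meta, file.path(out_dir, "meta_validation.csv"))
    jsonlite::write_json(
      list(marker_gene_ids = s$truth$marker_gene_ids,
           smoking_gene_ids = s$truth$smoking_gene_ids,
           outliers = v$truth$outliers),
      file.path(out_dir, "truth.json"), auto_unbox = FALSE, digits = NA)
    list(counts = s$counts, meta = s$meta, truth = s$truth, ct = v$ct,
         meta_val = v$meta)
  })

  disc <- stage("discover", {
    qc <- sample_qc(sim$counts, min_assigned = config$min_assigned,
                    max_replicate_cv = config$max_replicate_cv)
    for (i in seq_len(nrow(qc$dropped))) {
      info("QC drop %s (%s)", qc$dropped$sample_id[i], qc$dropped$reason[i])
    }
    m <- sim$counts$counts[, qc$kept, drop = FALSE]
    map <- sim$counts$replicate_of
    map <- map[names(map) %in% qc$kept & unname(map) %in% qc$kept]
    kept <- count_matrix(m, replicate_of = if (length(map)) map else NULL)
    merged <- merge_technical_replicates(kept)
    meta_subj <- sim$meta[match(colnames(merged$counts), sim$meta$sample_id), ]
    pca <- pca_summary(merged, pseudocount = config$pseudocount)

    is_t <- function(md) md$group == "tumour"
    de <- list(
      tumour_vs_smoker = de_test(merged, meta_subj,
                                 groupA = function(md) md$group == "healthy" &
                                   md$smoking %in% c("light", "heavy"),
                                 groupB = is_t, pseudocount = config$pseudocount),
      tumour_vs_nonsmoker = de_test(merged, meta_subj,
                                    groupA = function(md) md$group == "healthy" &
                                      md$smoking == "none",
                                    groupB = is_t, pseudocount = config$pseudocount),
      tumour_vs_all_healthy = de_test(merged, meta_subj,
                                      groupA = "healthy", groupB = "tumour",
                                      pseudocount = config$pseudocount)
    )
    de_all <- do.call(rbind, Map(function(d, nm) {
      d$contrast <- nm
      d
    }, de, names(de)))
    write_result(de_all, file.path(out_dir, "de_results.tsv"))
    jsonlite::write_json(list(variance_explained = pca$variance_explained),
                         file.path(out_dir, "pca.json"), digits = NA)

    sig <- significant_in_all_contrasts(de$tumour_vs_all_healthy,
                                        alpha = config$alpha)
    thresholds <- cascade_config(min_base_mean = config$min_base_mean,
                                 min_log2fc = config$min_log2fc,
                                 min_diff = config$min_diff,
                                 max_diff = config$max_diff,
                                 max_outliers_per_group = config$max_outliers)
    norm <- normalize_counts(merged)
    if (length(sig)) {
      sl <- filter_cascade(sig, de$tumour_vs_all_healthy, norm, meta_subj,
                           thresholds, pseudocount = config$pseudocount)
      funnel <- attr(sl, "funnel")
    } else {
      sl <- NULL
      funnel <- c(candidates = 0, base_mean = 0, log2fc = 0,
                  diff_window = 0, outlier_rule = 0)
    }
    if (!is.null(sl)) write_result(sl, file.path(out_dir, "shortlist.tsv"))
    jsonlite::write_json(as.list(funnel), file.path(out_dir, "cascade_funnel.json"),
                         auto_unbox = TRUE, digits = NA)
    info("discovery funnel: %s",
         paste(sprintf("%s n=%d", names(funnel), funnel), collapse = " -> "))
    list(de = de, shortlist = sl, funnel = funnel, pca = pca,
         dropped = qc$dropped)
  })

  qp <- stage("qpcr", {
    expr <- relative_expression(sim$ct, housekeeping = config$housekeeping,
                                max_sd = config$max_sd, rescue = config$rescue)
    panel_genes <- setdiff(unique(expr$gene), config$housekeeping)
    comp <- cohort_marker_stats(expr, sim$meta_val, panel_genes)
    write_result(expr, file.path(out_dir, "expression.tsv"))
    write_result(comp, file.path(out_dir, "comparisons.tsv"))
    list(expr = expr, comparisons = comp, genes = panel_genes)
  })

  rocres <- stage("roc", {
    grp <- setNames(sim$meta_val$group, sim$meta_val$sample_id)
    X <- expression_matrix(qp$expr, qp$genes)
    use <- grp[rownames(X)] %in% c("healthy", "tumour")
    X2 <- X[use, , drop = FALSE]
    lab <- grp[rownames(X2)] == "tumour"
    single <- do.call(rbind, lapply(qp$genes, function(g) {
      ok <- !is.na(X2[, g])
      r <- roc_analysis(X2[ok, g], lab[ok])
      data.frame(gene = g, auc = r$auc, youden_cutoff = r$youden_cutoff,
                 se = r$se_at_cutoff, sp = r$sp_at_cutoff,
                 pct_false_pos = r$pct_false_pos,
                 pct_false_neg = r$pct_false_neg, stringsAsFactors = FALSE)
    }))
    write_result(single, file.path(out_dir, "roc.tsv"))
    list(single = single, X = X2, labels = lab)
  })

  combi <- stage("combi", {
    combos <- evaluate_combos(rocres$X, rocres$labels, qp$genes,
                              min_size = config$combo_min_size,
                              max_size = min(config$combo_max_size,
                                             length(qp$genes)),
                              method = config$method, ridge = config$ridge)
    write_result(combos, file.path(out_dir, "combos.tsv"))
    sex <- setNames(sim$meta_val$sex, sim$meta_val$sample_id)
    strat <- tryCatch(
      stratified_eval(rocres$X, rocres$labels, sex[rownames(rocres$X)],
                      qp$genes, method = config$method, ridge = config$ridge),
      error = function(e) NULL)
    if (!is.null(strat)) write_result(strat, file.path(out_dir, "stratified.tsv"))
    list(combos = combos, stratified = strat)
  })

  report <- make_report(
    list(funnel = disc$funnel, roc = rocres$single, combos = combi$combos,
         stratified = combi$stratified, comparisons = qp$comparisons,
         dropped = disc$dropped, pca = disc$pca, config = config),
    out_dir)
  invisible(report)
}

fmt_or_na <- function(x, fmt) if (is.null(x) || !length(x)) "NA" else sprintf(fmt, x)

#' Render the run report
#'
#' Writes `report.md` and `report.json` from the stage artifacts, rounding
#' AUCs to 2 decimals and percentages to 1 decimal. Missing artifacts are
#' listed as "not run", never fabricated.
#'
#' @param artifacts Named list with any of `funnel`, `roc`, `combos`,
#'   `stratified`, `comparisons`, `dropped`, `pca`, `config`.
#' @param out_dir Output directory.
#' @return List of class `run_report`.
#' @export
make_report <- function(artifacts, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- artifacts$config
  lines <- c("# Biomarker pipeline run report", "")
  if (!is.null(cfg)) {
    lines <- c(lines,
               sprintf("- seed: %d", cfg$seed),
               sprintf("- config hash: %s", config_hash(unclass(cfg))),
               sprintf("- package version: %s",
                       as.character(utils::packageVersion("swabmark"))), "")
  }
  lines <- c(lines, "## Discovery funnel", "")
  if (!is.null(artifacts$funnel)) {
    f <- artifacts$funnel
    lines <- c(lines, paste(sprintf("%s: n = %d", names(f), f),
                            collapse = " -> "), "")
  } else lines <- c(lines, "not run", "")
  if (!is.null(artifacts$pca)) {
    ve <- artifacts$pca$variance_explained
    lines <- c(lines, sprintf("PCA: PC1 %.0f%%, PC2 %.0f%%", 100 * ve[1],
                              100 * ve[min(2, length(ve))]), "")
  }
  lines <- c(lines, "## Single markers (healthy vs tumour)", "")
  if (!is.null(artifacts$roc)) {
    r <- artifacts$roc
    lines <- c(lines, "| marker | AUC | SE % | SP % |", "|---|---|---|---|",
               sprintf("| %s | %.2f | %.1f | %.1f |", r$gene, r$auc,
                       100 * r$se, 100 * r$sp), "")
  } else lines <- c(lines, "not run", "")
  lines <- c(lines, "## Marker combinations", "")
  if (!is.null(artifacts$combos)) {
    cb <- artifacts$combos
    lines <- c(lines, "| combo | AUC | SE % | SP % | cutoff |",
               "|---|---|---|---|---|",
               sprintf("| %s | %.2f | %.1f | %.1f | %.3g |", cb$combo,
                       cb$auc, 100 * cb$se, 100 * cb$sp, cb$youden_cutoff),
               "(no multiplicity correction is applied across combinations)",
               "")
  } else lines <- c(lines, "not run", "")
  lines <- c(lines, "## Sex-stratified analysis", "")
  if (!is.null(artifacts$stratified)) {
    st <- artifacts$stratified
    lines <- c(lines, "| stratum | marker set | AUC |", "|---|---|---|",
               sprintf("| %s | %s | %.2f |", st$stratum, st$combo, st$auc), "")
  } else lines <- c(lines, "not run", "")
  writeLines(lines, file.path(out_dir, "report.md"))
  json <- list(
    funnel = if (is.null(artifacts$funnel)) "not run" else
      as.list(artifacts$funnel),
    single_markers = if (is.null(artifacts$roc)) "not run" else
      artifacts$roc,
    combos = if (is.null(artifacts$combos)) "not run" else
      as.data.frame(artifacts$combos),
    stratified = if (is.null(artifacts$stratified)) "not run" else
      as.data.frame(artifacts$stratified),
    qc_dropped = if (is.null(artifacts$dropped)) "not run" else
      artifacts$dropped,
    provenance = if (is.null(cfg)) NULL else
      list(seed = cfg$seed, config_hash = config_hash(unclass(cfg)))
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  structure(json, class = "run_report")
}
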