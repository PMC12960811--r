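# Synthetic cohort generator.
#
# Emulates the data structure the analysis assumes: NB-distributed RNA-seq
# counts for a small all-male discovery cohort (tumour vs healthy smokers and
# non-smokers, with technical replicates), and triplicate RT-qPCR Ct values
# normalised to a housekeeping gene across the four validation groups with a
# sex-dependent effect attenuation and injected outliers. Everything is
# deterministic given the design seed; each output artifact draws from its own
# named RNG substream so adding one artifact never perturbs another.

#' Simulation design: cohort sizes and gene panel dimensions
#'
#' @param n_tumour,n_healthy_smoker,n_healthy_nonsmoker Discovery cohort sizes
#'   (all male, sequenced with technical replicates).
#' @param validation Named list `list(male = c(...), female = c(...))`, each a
#'   named count vector over the four groups `healthy`, `tumour`,
#'   `post_therapy`, `high_risk`.
#' @param n_genes Total number of simulated genes (including housekeeping).
#' @param n_marker_genes Number of genes carrying the tumour effect.
#' @param n_smoking_genes Number of genes carrying the smoking effect.
#' @param technical_replicates_per_sample Sequencing replicates per subject.
#' @param seed Master RNG seed; all randomness derives from it.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(n_tumour = 4, n_healthy_smoker = 3,
                       n_healthy_nonsmoker = 3,
                       validation = list(
                         male = c(healthy = 12, tumour = 14,
                                  post_therapy = 12, high_risk = 11),
                         female = c(healthy = 19, tumour = 11,
                                    post_therapy = 0, high_risk = 0)
                       ),
                       n_genes = 2000, n_marker_genes = 40,
                       n_smoking_genes = 40,
                       technical_replicates_per_sample = 2,
                       seed = 1L) {
  for (v in c(n_tumour, n_healthy_smoker, n_healthy_nonsmoker, n_genes,
              n_marker_genes, n_smoking_genes,
              technical_replicates_per_sample)) {
    if (!is_count_scalar(v)) stop_fmt("design counts must be non-negative integers")
  }
  if (n_marker_genes + n_smoking_genes + 1L > n_genes) {
    stop_fmt("marker + smoking genes (+ housekeeping) exceed n_genes")
  }
  for (sx in names(validation)) {
    v <- validation[[sx]]
    if (!all(GROUP_LEVELS %in% names(v)) || any(v < 0)) {
      stop_fmt("validation sizes for '%s' must cover all four groups", sx)
    }
  }
  structure(list(n_tumour = n_tumour, n_healthy_smoker = n_healthy_smoker,
                 n_healthy_nonsmoker = n_healthy_nonsmoker,
                 validation = validation, n_genes = n_genes,
                 n_marker_genes = n_marker_genes,
                 n_smoking_genes = n_smoking_genes,
                 technical_replicates_per_sample = technical_replicates_per_sample,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Default study design
#'
#' Mirrors the study scale: discovery cohort of 4 tumour / 3 healthy-smoker /
#' 3 healthy non-smoker males; validation males 12 healthy / 14 tumour /
#' 12 post-therapy / 11 high-risk and females 19 healthy / 11 tumour.
#'
#' @param seed Master RNG seed.
#' @return A [sim_design()].
#' @export
default_design <- function(seed = 1L) sim_design(seed = seed)

#' Simulation parameters: noise model and effect sizes
#'
#' Counts follow a negative binomial with a single global dispersion and
#' log-normal library-size factors; Ct replicates carry Gaussian cycler noise.
#' Tumour and smoking effects are additive on the log2 scale; in females the
#' tumour effect is multiplied by `female_effect_attenuation`.
#'
#' @param baseline_log2_mean_range Range of per-gene baseline log2 NB means.
#' @param marker_log2_mean_range Baseline log2 mean range for marker genes.
#'   Markers are drawn as moderate-abundance genes: the discovery cascade's
#'   absolute-scale windows (base mean, base-mean difference) target exactly
#'   that regime, so a scenario planting markers at extreme abundance would
#'   not emulate the data structure the workflow assumes.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#'   The default 0.05 (biological CV ~ 22%) describes a deliberately
#'   homogeneous cohort in which planted markers really are robustly
#'   separated; heterogeneous-cohort scenarios should raise it.
#' @param library_size_log_sd SD of per-sample log library-size factors.
#' @param marker_log2fc Tumour log2 fold change planted in marker genes.
#' @param smoking_log2fc Smoking log2 fold change planted in smoking genes.
#' @param female_effect_attenuation Multiplier in \[0, 1\] applied to the
#'   tumour effect in female samples.
#' @param ct_intercept Ct of the housekeeping gene (abundance reference).
#' @param ct_biological_sd Between-subject SD (cycles, i.e. log2 units) of
#'   true relative abundance; this is what keeps validation AUCs away from 1,
#'   as in real cohorts.
#' @param ct_replicate_sd SD (cycles) of triplicate Ct noise.
#' @param housekeeping_gene Name of the stably expressed reference gene.
#' @param outlier_rate Probability a (sample, gene) Ct is shifted.
#' @param outlier_log2_shift Magnitude (cycles) of the injected Ct shift.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(baseline_log2_mean_range = c(1, 9),
                       marker_log2_mean_range = c(4, 7),
                       nb_dispersion = 0.05, library_size_log_sd = 0.2,
                       marker_log2fc = 3, smoking_log2fc = 2,
                       female_effect_attenuation = 0.3,
                       ct_intercept = 20, ct_biological_sd = 1.5,
                       ct_replicate_sd = 0.25,
                       housekeeping_gene = "MT-ATP6",
                       outlier_rate = 0.02, outlier_log2_shift = 4) {
  stopifnot(length(baseline_log2_mean_range) == 2L,
            diff(baseline_log2_mean_range) >= 0)
  assert_scalar_in(nb_dispersion, "nb_dispersion", 1e-12, Inf)
  assert_scalar_in(library_size_log_sd, "library_size_log_sd", 0, Inf)
  assert_scalar_in(female_effect_attenuation, "female_effect_attenuation", 0, 1)
  assert_scalar_in(ct_biological_sd, "ct_biological_sd", 0, Inf)
  assert_scalar_in(ct_replicate_sd, "ct_replicate_sd", 0, Inf)
  assert_scalar_in(outlier_rate, "outlier_rate", 0, 1)
  structure(list(baseline_log2_mean_range = baseline_log2_mean_range,
                 marker_log2_mean_range = marker_log2_mean_range,
                 nb_dispersion = nb_dispersion,
                 library_size_log_sd = library_size_log_sd,
                 marker_log2fc = marker_log2fc,
                 smoking_log2fc = smoking_log2fc,
                 female_effect_attenuation = female_effect_attenuation,
                 ct_intercept = ct_intercept,
                 ct_biological_sd = ct_biological_sd,
                 ct_replicate_sd = ct_replicate_sd,
                 housekeeping_gene = housekeeping_gene,
                 outlier_rate = outlier_rate,
                 outlier_log2_shift = outlier_log2_shift),
            class = "sim_params")
}

sim_gene_ids <- function(design, params) {
  n_null <- design$n_genes - design$n_marker_genes - design$n_smoking_genes - 1L
  c(params$housekeeping_gene,
    sprintf("MK%04d", seq_len(design$n_marker_genes)),
    sprintf("SM%04d", seq_len(design$n_smoking_genes)),
    sprintf("NG%05d", seq_len(n_null)))
}

# Shared gene-level ground truth (baseline means and planted effects); drawn
# from its own substream so counts and Ct artifacts agree on gene identity.
sim_truth <- function(design, params) {
  set.seed(substream_seed(design$seed, "genes"))
  gene_ids <- sim_gene_ids(design, params)
  r <- params$baseline_log2_mean_range
  base_log2 <- runif(design$n_genes, r[1], r[2])
  names(base_log2) <- gene_ids
  base_log2[params$housekeeping_gene] <- mean(r)  # stable reference gene
  marker_ids <- grep("^MK", gene_ids, value = TRUE)
  smoking_ids <- grep("^SM", gene_ids, value = TRUE)
  rm_ <- params$marker_log2_mean_range
  base_log2[marker_ids] <- runif(length(marker_ids), rm_[1], rm_[2])
  tumour_log2fc <- setNames(numeric(design$n_genes), gene_ids)
  tumour_log2fc[marker_ids] <- params$marker_log2fc
  smoking_log2fc <- setNames(numeric(design$n_genes), gene_ids)
  smoking_log2fc[smoking_ids] <- params$smoking_log2fc
  structure(list(marker_gene_ids = marker_ids,
                 smoking_gene_ids = smoking_ids,
                 baseline_log2_mean = base_log2,
                 tumour_log2fc = tumour_log2fc,
                 smoking_log2fc = smoking_log2fc,
                 samples = NULL, outliers = NULL),
            class = "sim_truth")
}

discovery_subjects <- function(design) {
  data.frame(
    subject_id = c(sprintf("T%02d", seq_len(design$n_tumour)),
                   sprintf("HS%02d", seq_len(design$n_healthy_smoker)),
                   sprintf("HN%02d", seq_len(design$n_healthy_nonsmoker))),
    group = rep(c("tumour", "healthy", "healthy"),
                c(design$n_tumour, design$n_healthy_smoker,
                  design$n_healthy_nonsmoker)),
    sex = "male",
    smoking = rep(c("heavy", "heavy", "none"),
                  c(design$n_tumour, design$n_healthy_smoker,
                    design$n_healthy_nonsmoker)),
    stringsAsFactors = FALSE
  )
}

#' Simulate the discovery RNA-seq cohort
#'
#' Draws NB counts `counts[g, s] ~ NB(mu = L_s * mu_g * 2^effects,
#' dispersion)` for the discovery design: tumour effect `marker_log2fc` in
#' marker genes of tumour samples, `smoking_log2fc` in smoking genes of
#' smokers. Technical replicates share the biological mean but are drawn
#' independently.
#'
#' @param design A [sim_design()].
#' @param params A [sim_params()].
#' @return A list with elements `counts` (a [count_matrix()] at replicate
#'   level, with replicate map), `meta` (a [sample_table()], one row per
#'   replicate column) and `truth` (gene-level ground truth and per-sample
#'   assignments).
#' @export
simulate_counts <- function(design, params = sim_params()) {
  stopifnot(inherits(design, "sim_design"), inherits(params, "sim_params"))
  subj <- discovery_subjects(design)
  if (design$n_tumour == 0 ||
      design$n_healthy_smoker + design$n_healthy_nonsmoker == 0) {
    stop_fmt("degenerate design: need >= 1 tumour and >= 1 healthy subject")
  }
  truth <- sim_truth(design, params)
  gene_ids <- names(truth$baseline_log2_mean)
  nrep <- max(1L, design$technical_replicates_per_sample)

  set.seed(substream_seed(design$seed, "counts"))
  L <- exp(rnorm(nrow(subj), 0, params$library_size_log_sd))
  eff <- outer(truth$tumour_log2fc, as.numeric(subj$group == "tumour")) +
    outer(truth$smoking_log2fc,
          as.numeric(subj$smoking %in% c("light", "heavy")))
  mu <- 2^(truth$baseline_log2_mean + eff) * rep(L, each = length(gene_ids))
  size <- 1 / params$nb_dispersion

  cols <- vector("list", nrow(subj) * nrep)
  ids <- character(nrow(subj) * nrep)
  rep_of <- character(0)
  k <- 0L
  for (s in seq_len(nrow(subj))) {
    for (r in seq_len(nrep)) {
      k <- k + 1L
      ids[k] <- if (nrep == 1L) subj$subject_id[s] else
        sprintf("%s_r%d", subj$subject_id[s], r)
      cols[[k]] <- rnbinom(length(gene_ids), mu = mu[, s], size = size)
      if (r > 1L) rep_of[ids[k]] <- sprintf("%s_r1", subj$subject_id[s])
    }
  }
  m <- do.call(cbind, cols)
  dimnames(m) <- list(gene_ids, ids)
  counts <- count_matrix(m, replicate_of = if (length(rep_of)) rep_of else NULL)

  meta <- sample_table(data.frame(
    sample_id = ids,
    subject_id = rep(subj$subject_id, each = nrep),
    group = rep(subj$group, each = nrep),
    sex = rep(subj$sex, each = nrep),
    smoking = rep(subj$smoking, each = nrep),
    swab_site = ifelse(rep(subj$group, each = nrep) == "tumour",
                       "lesion", NA),
    stringsAsFactors = FALSE
  ))
  truth$samples <- subj
  list(counts = counts, meta = meta, truth = truth)
}

validation_subjects <- function(design) {
  rows <- list()
  for (sx in names(design$validation)) {
    sizes <- design$validation[[sx]]
    for (g in GROUP_LEVELS) {
      n <- sizes[[g]]
      if (n > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("V_%s_%s_%02d", substr(sx, 1, 1), g, seq_len(n)),
          group = g, sex = sx,
          swab_site = if (g == "healthy") NA_character_ else "lesion",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate the RT-qPCR validation cohort
#'
#' For each sample and panel gene the true Ct is `ct_intercept - log2(relative
#' abundance)`, with the housekeeping gene as the constant abundance
#' reference; triplicates add iid Gaussian cycler noise. Tumour samples carry
#' the planted marker effect, attenuated by `female_effect_attenuation` in
#' females; post-therapy and high-risk samples sit at baseline. Outliers are
#' injected per (sample, gene) at `outlier_rate` by shifting the true Ct by
#' +/- `outlier_log2_shift` cycles.
#'
#' @param design A [sim_design()] (validation cohort sizes are used).
#' @param params A [sim_params()].
#' @param truth Gene-level truth from [simulate_counts()]; generated afresh
#'   when omitted so the Ct cohort can be simulated standalone.
#' @param genes Panel genes to assay; default the first four marker genes.
#' @return A list with `ct` (a [ct_table()] including the housekeeping gene),
#'   `meta` (a [sample_table()]) and `truth` (with per-sample assignments and
#'   the injected outlier list).
#' @export
simulate_ct <- function(design, params = sim_params(), truth = NULL,
                        genes = NULL) {
  stopifnot(inherits(design, "sim_design"), inherits(params, "sim_params"))
  if (is.null(truth)) truth <- sim_truth(design, params)
  if (!params$housekeeping_gene %in% names(truth$baseline_log2_mean)) {
    stop_fmt("housekeeping gene '%s' is not among the simulated genes",
             params$housekeeping_gene)
  }
  if (is.null(genes)) genes <- head(truth$marker_gene_ids, 4L)
  unknown <- setdiff(genes, names(truth$baseline_log2_mean))
  if (length(unknown)) {
    stop_fmt("unknown panel gene(s): %s", paste(unknown, collapse = ", "))
  }
  subj <- validation_subjects(design)
  if (is.null(subj) || !nrow(subj)) stop_fmt("validation design has no samples")

  hk <- params$housekeeping_gene
  base_rel <- truth$baseline_log2_mean[genes] - truth$baseline_log2_mean[hk]
  att <- ifelse(subj$sex == "female", params$female_effect_attenuation, 1)
  # genes x samples matrix of true log2 abundance relative to housekeeping
  rel <- outer(base_rel, rep(0, nrow(subj))) +
    outer(truth$tumour_log2fc[genes],
          as.numeric(subj$group == "tumour") * att)
  set.seed(substream_seed(design$seed, "biology"))
  rel <- rel + matrix(rnorm(length(rel), 0, params$ct_biological_sd),
                      nrow(rel), ncol(rel))
  true_ct <- params$ct_intercept - rel

  set.seed(substream_seed(design$seed, "outliers"))
  out_mask <- matrix(runif(length(true_ct)) < params$outlier_rate,
                     nrow(true_ct), ncol(true_ct))
  out_sign <- matrix(sign(runif(length(true_ct)) - 0.5),
                     nrow(true_ct), ncol(true_ct))
  true_ct <- true_ct + out_mask * out_sign * params$outlier_log2_shift
  outliers <- if (any(out_mask)) {
    idx <- which(out_mask, arr.ind = TRUE)
    data.frame(sample_id = subj$sample_id[idx[, 2]], gene = genes[idx[, 1]],
               shift = (out_sign * params$outlier_log2_shift)[idx],
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = character(0), gene = character(0),
               shift = numeric(0))
  }

  all_genes <- c(genes, hk)
  full_ct <- rbind(true_ct, matrix(params$ct_intercept, 1, ncol(true_ct)))
  set.seed(substream_seed(design$seed, "ct"))
  rows <- expand.grid(replicate = 1:3, gene = all_genes,
                      sample_id = subj$sample_id, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  mu_ct <- rep(as.vector(full_ct), each = 3L)
  ct <- pmin(45, pmax(0, mu_ct + rnorm(length(mu_ct), 0, params$ct_replicate_sd)))
  tab <- ct_table(data.frame(sample_id = rows$sample_id, gene = rows$gene,
                             replicate = rows$replicate, ct = ct,
                             stringsAsFactors = FALSE))
  meta <- sample_table(subj)
  truth$samples <- subj
  truth$outliers <- outliers
  list(ct = tab, meta = meta, truth = truth)
}
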