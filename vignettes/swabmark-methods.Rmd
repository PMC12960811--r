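---
title: "swabmark: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{swabmark: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swabmark)
```

`swabmark` implements a swab-based mRNA biomarker workflow for oral and
oropharyngeal squamous cell carcinoma: RNA-seq candidate discovery in a
small pilot cohort, RT-qPCR validation in a larger four-group cohort, and
combinatorial panel evaluation by ROC analysis. This vignette explains the
statistical choices stage by stage, documents every tunable parameter, and
is explicit about what the bundled simulator does and does not emulate.

## Discovery on RNA-seq counts

**Normalisation.** Size factors are classical median-of-ratios: per gene
the reference is the geometric mean of its counts across samples (genes
containing any zero are excluded from the reference set), and a sample's
factor is the median of `count / reference` over reference genes. Only
factor *ratios* are identified; scaling one sample's depth by `k` moves
every factor through the geometric-mean reference, so normalised profiles
are invariant to depth changes up to a single global constant. Requesting
factors for a sample with no usable reference gene (for example an
all-zero column) is an error rather than a silent fallback.

**Differential testing.** The per-gene test is a two-sided Welch *t* on
`log2(normalised counts + c)`, with Benjamini–Hochberg adjustment within
each contrast (tumour vs smokers, tumour vs non-smokers, tumour vs pooled
healthy), mirroring the three separate DEG counts a discovery analysis
reports. This is a deliberately transparent stand-in for an NB-GLM
pipeline such as DESeq2: the package's discovery contract is the filter
cascade downstream, not equivalence with shrinkage-based machinery, and a
Welch test on log counts is fully auditable against its closed form. The
vectorised implementation is cross-checked against `stats::t.test` to
1e-12 in the test suite. Genes with zero variance in both groups carry no
evidence and are reported with `t = 0, p = 1`.

**Pseudocount.** `c = 1` on the normalised scale, used for all logs, fold
changes and the outlier rule. It bounds behaviour at zero counts and is
standard practice; it is exposed as `pseudocount` throughout.

**Sample QC.** Samples are dropped when total assigned counts fall below
`min_assigned` (default 1000 in the pipeline configuration; set it to the
scale of your sequencing depth), or when a subject's technical replicates
disagree: per expressed gene the CV of `log2(count + 1)` across replicates
is computed, and the subject is dropped when the median CV exceeds
`max_replicate_cv` (default 0.5). The replicate-deviation rule is an
artifact definition — published workflows typically state only that
replicates "deviated" — and both thresholds are configuration values, not
science. QC never raises on data content; it records reasons.

**PCA.** Samples are observations, genes are centred (not scaled by
default, matching common RNA-seq QC practice; scaling is a flag), and the
variance explained comes from the singular values of `prcomp`. A constant
matrix yields an all-zero summary with a warning.

## The candidate shortlist

**Largest minimum fold change.** For a tumour-up candidate the robust
separation statistic is `min(tumour) / max(healthy)` on pseudocounted
normalised counts: the worst-case ratio pairing the least-expressing
tumour sample with the highest-expressing healthy sample. A value above 1
means the groups do not overlap at all, which is the property that lets a
candidate survive the jump from a 10-sample sequencing cohort to RT-qPCR
across a whole clinic population. Note the orientation: descriptions of
this statistic sometimes print the reciprocal (healthy over tumour); the
package follows the separation-ratio reading, where larger is better and
survivors are ranked by it in descending order.

**Filter cascade.** Applied in order to the significant, over-expressed
candidates (`p_adj < alpha`, `log2fc > 0` in the pooled-healthy contrast;
`alpha` default 0.05, strict inequality):

1. overall base mean `> 25` (strict),
2. `log2FC > 2` (strict),
3. tumour − healthy base-mean difference inside `[50, 3500]` (inclusive),
4. at most one outlier per group.

The cut points are the published defaults of the workflow the package
implements and live in `cascade_config()`. The outlier rule needs a
definition of "outlier" that published descriptions leave implicit; here
the separation threshold is the geometric mean of the two group medians,
and a sample on the wrong side of it counts. The funnel count after each
rule is reported so a run prints its own `131 → … → 4`-style story.

**Intersection switch.** Whether the initial significant set should come
from the pooled-healthy contrast alone or from the intersection of the
smoker and non-smoker contrasts is genuinely ambiguous in this design;
`significant_in_all_contrasts(..., intersect = TRUE)` provides the
intersection reading, with the pooled contrast as default.

## RT-qPCR quantification

Triplicates are aggregated per (sample, gene); when the replicate SD
exceeds `max_sd` (default 0.5 cycles, a common triplicate QC rule — the
underlying workflow states none) and `rescue = TRUE`, the single replicate
whose removal minimises the SD is dropped, and the well is flagged
`rescued` if the remaining pair is within tolerance, `high_sd` otherwise.
Fewer than two usable replicates make the well `missing`; a missing Ct is
encoded as NA, never as a sentinel such as 40, because 40 is a legitimate
Ct. ΔCt is `target − housekeeping`, relative expression `2^-ΔCt`, and the
pipeline is exactly invertible (`log2_rel_expr = housekeeping − target`)
for every usable row. Group statistics are computed on `log2_rel_expr`
(approximately normal), while fold changes are reported on the linear
scale as ratios of mean relative expression. Group comparisons are
two-sided Welch *t* tests; lesion and contralateral swabs flow through the
same contrast machinery as strata, with no paired test, since the target
workflow reports only group-level comparisons. Efficiency-corrected
(Pfaffl) quantification and standard curves are out of scope.

## ROC and panel evaluation

The AUC is the Mann–Whitney statistic computed from midranks (ties count
one half); the curve takes thresholds at the unique scores plus infinite
sentinels with positive calls at `score >= threshold`, and its trapezoidal
area equals the pair-counting AUC to numerical precision. The Youden
cutoff maximises `J = SE + SP − 1` by exhaustive scan; internally the
objective is the integer `tp * n_neg + tn * n_pos`, so mathematical ties
are exact and always break toward the smallest cutoff. False-call
percentages use the total evaluated cohort as denominator — the reading
most consistent with reporting "3.9%" alongside SE = SP = 92.3% in a
26-sample comparison — which is a documented interpretation, not a fact.

**Combined scores.** The default combination is an L2-penalised logistic
model on standardised log2 relative expressions (`ridge` default 1e-6 —
small enough to leave probabilities essentially unpenalised, large enough
to keep the fit defined under perfect separation). This mirrors GLM-based
panel tools and puts the operating cutoff on a probability scale;
`mean_z` (the mean of per-marker z-scores) is offered as a transparent
alternative. Constant markers are dropped with a warning. Evaluation is
in-sample, as in pilot-scale panel reports; no cross-validation is applied
by default and no multiplicity correction is made across the enumerated
combinations (the report notes this). In-sample logistic scores
over-estimate panel AUC on null data, which is visible in the test suite's
chance-level checks; `mean_z` does not fit anything and sits at chance.

`evaluate_combos()` enumerates all subsets with sizes in
`[min_size, max_size]` (`min_size >= 2`; single markers go through
`roc_analysis()` directly) and ranks by AUC, then Youden J, then smaller
panel size. `stratified_eval()` repeats single-marker and panel analyses
independently per stratum (for instance sex) and reports cross-stratum AUC
differences, skipping one-class strata with a warning.

## What the simulator emulates — and what it does not

`simulate_counts()` draws `NB(mu = L_s * mu_g * 2^effects, dispersion)`
counts for the discovery design (4 tumour / 3 healthy-smoker /
3 healthy non-smoker males, technical replicates included), with
log-normal library factors (`library_size_log_sd`, default 0.2). Marker
genes carry `marker_log2fc` (default 3) in tumour samples; smoking genes
carry `smoking_log2fc` (default 2) in smokers. `simulate_ct()` builds the
validation cohort (males 12/14/12/11 across healthy/tumour/post-therapy/
high-risk; females 19 healthy and 11 tumour) with true
`Ct = ct_intercept − log2(relative abundance)`, Gaussian between-subject
biological spread (`ct_biological_sd`, default 1.5 cycles), iid triplicate
noise (`ct_replicate_sd`, default 0.25 cycles), and outliers injected per
well at `outlier_rate` (default 0.02) by shifting the true Ct by
±`outlier_log2_shift` (default 4 cycles). In females the tumour effect is
multiplied by `female_effect_attenuation` (default 0.3), reproducing the
*structure* of weaker female discrimination as a tunable scenario — not as
a biological claim. Each artifact (gene truth, counts, biology, Ct noise,
outliers) draws from its own named RNG substream derived from the master
seed, so adding one artifact never perturbs the others, and identical
designs give bit-identical output.

Deliberate scenario choices, made once:

* **Markers are moderate-abundance genes** (`marker_log2_mean_range`
  default `[4, 7]` on the log2 normalised-count scale). The cascade's
  absolute windows (base mean > 25, difference ≤ 3500) target exactly that
  regime; planting markers at extreme abundance would test the scenario,
  not the method.
* **`nb_dispersion` default 0.05** (biological CV ≈ 22%): a deliberately
  homogeneous cohort in which planted markers genuinely are robustly
  separated, which is what the recovery checks require. Real mixed cohorts
  are more dispersed (0.1–0.5); at higher dispersion the 4-vs-6 discovery
  stage loses power and recovery degrades — that is a property of tiny
  pilot designs, and the parameter is exposed precisely so users can
  explore it.
* **Post-therapy and high-risk samples sit at baseline** expression. The
  workflow's premise is that good markers return to baseline after therapy
  and are not inflamed in high-risk mucosa; a marker violating this is a
  different scenario (tune the per-group effects through the truth object).

Consequently, passing tests show that the pipeline recovers what it is
designed to recover under its own assumptions. They do not show that real
swab RNA-seq obeys a single global dispersion, that qPCR noise is Gaussian
and homoscedastic, that markers act additively on the log scale, or that
female attenuation is multiplicative — those are model conveniences, and
per-gene dispersion or alternative effect structures are extension points,
not claims.

## Numerical and degenerate-input policy

* Ties: AUC uses midranks; Youden ties break toward the smallest cutoff on
  an exact integer objective; combination ranking breaks AUC ties by J,
  then by smaller panel size.
* Welch on constant data: equal constant groups give `t = 0, p = 1`;
  unequal constant groups give `t = ±Inf, p = 0` (the base `t.test` either
  raises or returns NaN there).
* Degenerate inputs raise early with named offenders: missing genes in the
  cascade, unknown group labels with their row numbers, duplicate
  (sample, gene, replicate) triples, one-class label vectors, all-constant
  marker sets.
* Readers never silently drop rows: every normalised or rejected record is
  reported with its line number, and group-label synonyms
  (`"Tumor"`, `"post-therapy"`, `"high risk"`) are mapped
  case-insensitively with a message.

## Scale of the bundled checks

The test suite and the acceptance script run entirely on simulated data at
desk scale, chosen as the package's own working sizes: discovery cohorts
of 2000 genes with 40 planted markers over 50 seeds for recovery, 100–250
random instances for oracle equivalence per operation (1000 for AUC pair
counting), 2000 samples per class for the Gaussian AUC limit, and 50–100
seeds for ΔCt effect recovery. The numbers any given run prints (for
instance the worked example in the README) are produced by that run's
seed.

## Known limitations

* The discovery test is a Welch *t* on log counts, not an NB GLM; with
  n = 4 vs 6 its power and calibration depend on count levels, and
  dispersion shrinkage, independent filtering and LFC shrinkage are
  explicitly out of scope.
* Panel metrics are in-sample; with dozens of samples and up to four
  markers the optimism is modest but real, and there is no external-cohort
  validation, no AUC confidence interval and no DeLong test.
* The simulator's defaults describe a favourable, homogeneous scenario;
  they are scenario parameters, not estimates of any real cohort.
* Cohort sizes follow the validation table of the emulated study design;
  the female arm has no post-therapy or high-risk groups, so sex-stratified
  four-group comparisons are only possible for males.
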