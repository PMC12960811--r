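Package: swabmark
Title: Swab-Based mRNA Biomarker Discovery, Validation and Panel ROC Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for selecting and evaluating diagnostic mRNA
    biomarker panels from non-invasive swab samples. Covers RNA-seq candidate
    discovery with a robust largest-minimum fold-change statistic and a hard
    filter cascade (base mean, log2 fold change, base-mean difference window,
    per-group outlier rule), RT-qPCR delta-Ct relative quantification with
    triplicate quality control and Welch group comparisons, and combinatorial
    marker-panel ROC analysis with Youden-index operating cutoffs. A
    negative-binomial cohort simulator generates counts, Ct tables, clinical
    metadata and ground truth so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
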