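test_that("median-of-ratios size factors follow their algebra", {
  m <- matrix(c(2, 4, 8, 2, 4, 8), 3, 2)
  cm <- make_counts(m)
  expect_equal(unname(size_factors(cm)), c(1, 1))
  # doubling a sample doubles its factor exactly (zero-free fixture)
  m2 <- cbind(m[, 1], m[, 1] * 2)
  expect_equal(unname(size_factors(make_counts(m2))),
               unname(size_factors(make_counts(m2))[1]) * c(1, 2))
  # all-zero sample cannot be normalised
  expect_error(size_factors(make_counts(cbind(c(1, 2, 3), 0))),
               "positive|reference")
})

test_that("normalisation removes pure depth differences", {
  set.seed(21)
  m <- matrix(rpois(60, 50) + 1, 10, 6)
  cm <- make_counts(m)
  base <- normalize_counts(cm)
  for (k in c(2, 5)) {
    m2 <- m
    m2[, k] <- m2[, k] * 3L
    scaled <- normalize_counts(make_counts(m2))
    # size factors are identified up to a common constant, so the depth
    # change must vanish from every profile up to one global scale
    ratio <- scaled / base
    expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-12)
    # relative composition of the inflated sample is exactly restored
    expect_equal(scaled[, k] / sum(scaled[, k]), base[, k] / sum(base[, k]),
                 tolerance = 1e-12)
  }
})

test_that("technical replicates merge by summation", {
  m <- matrix(c(1, 2, 3, 4), 2, 2)
  cm <- make_counts(m, samples = c("a_r1", "a_r2"),
                    replicate_of = c(a_r2 = "a_r1"))
  merged <- merge_technical_replicates(cm)
  expect_equal(unname(merged$counts[, 1]), c(4, 6))
  expect_equal(ncol(merged$counts), 1L)
  # identity without a map
  cm2 <- make_counts(m)
  expect_identical(merge_technical_replicates(cm2)$counts, cm2$counts)
  # three replicates conserve per-gene totals
  m3 <- matrix(rpois(15, 20), 3, 5,
               dimnames = list(NULL, c("a_r1", "a_r2", "a_r3", "b_r1", "b_r2")))
  cm3 <- count_matrix(matrix(as.integer(m3), 3, 5,
                             dimnames = list(c("g1", "g2", "g3"), colnames(m3))),
                      replicate_of = c(a_r2 = "a_r1", a_r3 = "a_r1",
                                       b_r2 = "b_r1"))
  merged3 <- merge_technical_replicates(cm3)
  expect_equal(rowSums(merged3$counts), rowSums(cm3$counts))
  expect_equal(colnames(merged3$counts), c("a_r1", "b_r1"))
  # replicate of a replicate is rejected
  cm4 <- make_counts(matrix(1:6, 2, 3), samples = c("a", "b", "c"),
                     replicate_of = c(b = "a", c = "b"))
  expect_error(merge_technical_replicates(cm4), "replicate of a replicate")
})

test_that("sample QC drops low-depth and discordant-replicate samples", {
  set.seed(3)
  base <- as.integer(2^runif(200, 2, 10))
  m <- cbind(base, base, base + rpois(200, 5), sample(base), 0)
  cm <- make_counts(m, samples = c("a_r1", "a_r2", "b_r1", "b_r2", "c"),
                    replicate_of = c(a_r2 = "a_r1", b_r2 = "b_r1"))
  qc <- sample_qc(cm, min_assigned = 1000, max_replicate_cv = 0.05)
  expect_true("c" %in% qc$dropped$sample_id)
  expect_equal(qc$dropped$reason[qc$dropped$sample_id == "c"], "low_assigned")
  # identical replicates (subject a) are kept
  expect_true(all(c("a_r1", "a_r2") %in% qc$kept))
  # scrambled replicate pair (subject b) is discordant and dropped
  expect_true(all(c("b_r1", "b_r2") %in% qc$dropped$sample_id))
  expect_true(all(qc$dropped$reason[qc$dropped$sample_id %in%
                                      c("b_r1", "b_r2")] ==
                    "replicate_deviation"))
})

test_that("de_test matches the Welch and BH oracles", {
  set.seed(77)
  m <- matrix(rnbinom(50 * 9, mu = 80, size = 10), 50, 9)
  cm <- make_counts(m)
  meta <- make_meta(colnames(cm$counts),
                    rep(c("healthy", "tumour"), c(5, 4)))
  de <- de_test(cm, meta, "healthy", "tumour")
  lg <- log2(normalize_counts(cm) + 1)
  for (i in c(1, 17, 50)) {
    ref <- t.test(lg[i, 6:9], lg[i, 1:5], var.equal = FALSE)
    expect_equal(de$p_value[i], ref$p.value, tolerance = 1e-12)
    expect_equal(de$t_stat[i], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(de$df[i], unname(ref$parameter), tolerance = 1e-12)
  }
  expect_equal(de$p_adj, bf_bh(de$p_value), tolerance = 1e-14)
  expect_true(all(de$p_adj >= de$p_value))
  # adjusted values are monotone in raw p
  ord <- order(de$p_value)
  expect_true(all(diff(de$p_adj[ord]) >= -1e-15))
})

test_that("identical groups give null fold changes and BH identities hold", {
  m <- matrix(rep(c(10, 40, 160), 4), 3, 4)
  cm <- make_counts(m)
  meta <- make_meta(colnames(cm$counts),
                    rep(c("healthy", "tumour"), each = 2))
  de <- de_test(cm, meta, "healthy", "tumour")
  expect_equal(de$log2fc, rep(0, 3))
  # single-gene BH identity p_adj = p, and the textbook 3-vector example
  expect_equal(bf_bh(0.02), 0.02)
  expect_equal(bf_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), c(0.03, 0.03, 0.03))
  # BH equals the step-up oracle on random vectors
  set.seed(5)
  for (m_ in c(1, 7, 100)) {
    p <- runif(m_)
    expect_equal(p.adjust(p, "BH"), bf_bh(p), tolerance = 1e-14)
  }
  expect_error(de_test(cm, meta, "healthy", "high_risk"), ">= 2 samples")
})

test_that("PCA variance summary agrees with a dense eigendecomposition", {
  # two distinct samples always lie on a line: PC1 captures everything
  m <- make_counts(matrix(c(2, 8, 32, 64, 16, 4), 3, 2))
  ps <- pca_summary(m)
  expect_equal(ps$variance_explained[1], 1, tolerance = 1e-10)
  # toy matrix vs eigen oracle
  set.seed(8)
  m2 <- make_counts(matrix(rpois(15, 60) + 1, 5, 3))
  ps2 <- pca_summary(m2)
  lg <- t(log2(normalize_counts(m2) + 1))
  lg <- lg[, apply(lg, 2, var) > 0, drop = FALSE]
  ev <- eigen(cov(scale(lg, scale = FALSE)))$values
  ev <- ev[ev > 1e-12]
  expect_equal(ps2$variance_explained[seq_along(ev)] * sum(ev), ev,
               tolerance = 1e-8)
  expect_lte(sum(ps2$variance_explained), 1 + 1e-12)
  expect_true(all(diff(ps2$variance_explained) <= 1e-12))
  # constant matrix: all-zero variance with a warning
  expect_warning(ps3 <- pca_summary(make_counts(matrix(5, 4, 3))), "constant")
  expect_true(all(ps3$variance_explained == 0))
})
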