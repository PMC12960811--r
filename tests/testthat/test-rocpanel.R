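test_that("AUC equals exhaustive pair counting, with ties worth one half", {
  expect_equal(auc(c(1, 2, 10, 20), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(3, 6), rep(c(0, 1), 3)), 0.5)
  # 13 vs 13 fixture: (144 + 12) / 169 by counting all pairs
  scores <- c(rep(0.6, 12), 0.3, rep(0.2, 12), 0.7)
  labels <- rep(c(1, 0), each = 13)
  expect_equal(auc(scores, labels), (144 + 12) / 169)
  expect_equal(bf_auc(scores, labels), (144 + 12) / 169)
  # random instances with heavy ties
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    s <- sample(round(runif(n, 0, 4), 1))
    l <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    expect_equal(auc(s, l), bf_auc(s, l), tolerance = 1e-14)
    # sign reversal flips the AUC
    expect_equal(auc(-s, l), 1 - auc(s, l), tolerance = 1e-14)
    # invariance under strictly increasing transforms
    expect_equal(auc(exp(s), l), auc(s, l), tolerance = 1e-14)
  }
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("the ROC curve is consistent with the pair-counting AUC", {
  r <- roc_analysis(c(1, 0), c(1, 0))
  expect_true(any(r$curve$sensitivity == 1 & r$curve$specificity == 1))
  set.seed(7)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    s <- round(runif(n, 0, 3), 1)
    l <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    r <- roc_analysis(s, l)
    expect_equal(swabmark:::trapezoid_auc(r$curve), r$auc, tolerance = 1e-12)
  }
})

test_that("Youden cutoff equals a brute-force threshold scan", {
  # perfect separation: J = 1, no false calls
  y <- youden_cutoff(c(1, 2, 10, 20), c(0, 0, 1, 1))
  expect_equal(y$j, 1)
  expect_equal(unname(y$confusion), c(2, 0, 2, 0))
  expect_equal(y$pct_false_pos + y$pct_false_neg, 0)
  set.seed(12)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    s <- round(runif(n, 0, 3), 1)
    l <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    y <- youden_cutoff(s, l)
    ref <- bf_youden(s, l)
    expect_equal(y$cutoff, ref$cutoff)
    expect_equal(y$j, ref$j, tolerance = 1e-12)
    # shifting all scores shifts the cutoff, J unchanged
    y2 <- youden_cutoff(s + 2.5, l)
    expect_equal(y2$cutoff, y$cutoff + 2.5, tolerance = 1e-12)
    expect_equal(y2$j, y$j, tolerance = 1e-12)
  }
})

test_that("the 13/13 overlap fixture reports the expected operating point", {
  fx <- confusion_fixture()
  r <- roc_analysis(fx$scores, fx$labels)
  expect_equal(unname(r$confusion), c(tp = 12, fp = 1, tn = 12, fn = 1),
               ignore_attr = TRUE)
  expect_equal(r$se_at_cutoff, 12 / 13)
  expect_equal(r$sp_at_cutoff, 12 / 13)
  expect_equal(sprintf("%.1f", 100 * r$se_at_cutoff), "92.3")
  expect_equal(r$pct_false_pos, 100 / 26)
  expect_equal(r$pct_false_neg, 100 / 26)
})

test_that("marker panels combine markers and expose model methods", {
  set.seed(41)
  n <- 30
  lab <- rep(c(0, 1), each = n / 2)
  x <- cbind(strong = lab * 3 + rnorm(n, sd = 0.3),
             weak = lab * 0.5 + rnorm(n),
             noise = rnorm(n))
  fit <- marker_panel(x, lab, c("strong", "weak"))
  expect_s3_class(fit, "marker_panel")
  expect_gt(fit$roc$auc, 0.95)
  expect_true(all(fit$scores >= 0 & fit$scores <= 1))
  # predict on the training data reproduces the in-sample scores
  expect_equal(unname(predict(fit, x)), unname(fit$scores), tolerance = 1e-6)
  cls <- predict(fit, x, type = "class")
  expect_equal(unname(cls), unname(fit$scores >= fit$roc$youden_cutoff))
  expect_named(coef(fit), c("(Intercept)", "strong", "weak"))
  expect_equal(length(residuals(fit)), n)
  expect_output(print(fit), "marker_panel")
  # perfectly separable pair scores the classes perfectly
  x2 <- cbind(a = c(rnorm(8), rnorm(8) + 10), b = c(rnorm(8), rnorm(8) + 8))
  expect_equal(marker_panel(x2, rep(c(0, 1), each = 8))$roc$auc, 1)
  # mean_z with one marker reduces to its standardised values
  fz <- marker_panel(x, lab, "strong", method = "mean_z")
  expect_equal(unname(fz$scores),
               as.numeric(scale(x[, "strong"])), tolerance = 1e-12)
  # constant markers are dropped with a warning; all constant is an error
  xc <- cbind(x, flat = 1)
  expect_warning(fitc <- marker_panel(xc, lab, c("strong", "flat")), "constant")
  expect_equal(fitc$markers, "strong")
  expect_error(suppressWarnings(marker_panel(xc, lab, "flat")), "constant")
})

test_that("ridge keeps a noise marker from sinking a strong marker", {
  deltas <- vapply(1:10, function(seed) {
    set.seed(600 + seed)
    n <- 60
    lab <- rep(c(0, 1), each = n / 2)
    x <- cbind(strong = lab * 2 + rnorm(n), noise = rnorm(n))
    single <- auc(x[, "strong"], lab)
    combo <- auc(combo_score(x, lab, c("strong", "noise")), lab)
    combo - single
  }, 0)
  expect_true(all(deltas > -0.05))
})

test_that("combination enumeration has set semantics and the 2^4 - 5 count", {
  set.seed(17)
  n <- 26
  lab <- rep(c(0, 1), each = 13)
  x <- matrix(rnorm(n * 4), n,
              dimnames = list(NULL, c("cJUN", "SFN", "HSP90AB1", "STARD7")))
  x[lab == 1, ] <- x[lab == 1, ] + 1.5
  ce <- evaluate_combos(x, lab, colnames(x), min_size = 2, max_size = 4)
  expect_equal(nrow(ce), 11L)  # 6 pairs + 4 triples + 1 quadruple
  expect_equal(sort(table(ce$size), decreasing = TRUE),
               sort(table(c(rep(2, 6), rep(3, 4), rep(4, 1))), decreasing = TRUE),
               ignore_attr = TRUE)
  expect_equal(ce$rank, seq_len(11))
  expect_true(all(diff(ce$auc) <= 1e-12))
  # duplicated marker names collapse to the same set
  ce2 <- evaluate_combos(x, lab, c("cJUN", "SFN", "cJUN"), min_size = 2,
                         max_size = 2)
  expect_equal(nrow(ce2), 1L)
  expect_error(evaluate_combos(x, lab, colnames(x), min_size = 1), "min_size")
  expect_error(evaluate_combos(x, lab, colnames(x), max_size = 9), "max_size")
})

test_that("all-noise panels sit at chance level", {
  set.seed(23)
  n <- 300
  lab <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("m", 1:4)))
  ce_z <- evaluate_combos(x, lab, method = "mean_z")
  expect_lt(max(ce_z$auc), 0.62)
  expect_gt(min(ce_z$auc), 0.38)
  ce_l <- evaluate_combos(x, lab, method = "logistic")
  expect_lt(max(ce_l$auc), 0.65)
})

test_that("stratified evaluation reports per-stratum metrics and differences", {
  set.seed(52)
  n <- 40
  lab <- rep(c(0, 1), n / 2)
  x <- cbind(m1 = lab * 2 + rnorm(n), m2 = lab + rnorm(n))
  strata <- rep(c("male", "female"), each = n / 2)
  # identical strata: zero AUC difference
  xx <- rbind(x[1:20, ], x[1:20, ])
  ll <- c(lab[1:20], lab[1:20])
  st <- stratified_eval(xx, ll, strata, c("m1", "m2"))
  d <- attr(st, "auc_differences")
  expect_true(all(abs(d$auc_diff) < 1e-12))
  # a one-class stratum is skipped with a warning
  expect_warning(
    st2 <- stratified_eval(x, c(rep(1, 20), rep(0, 10), lab[31:40]),
                           strata, c("m1", "m2")),
    "skipped")
  expect_equal(unique(st2$stratum), "female")
})
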