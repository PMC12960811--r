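make_ct <- function(...) {
  rows <- list(...)
  ct_table(do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = r[[1]], gene = r[[2]],
               replicate = seq_along(r[[3]]), ct = r[[3]],
               stringsAsFactors = FALSE)
  })))
}

test_that("triplicate aggregation applies the rescue rule", {
  agg <- aggregate_triplicates(make_ct(list("s1", "SFN", c(25, 25, 25))))
  expect_equal(agg$mean_ct, 25)
  expect_equal(agg$ct_sd, 0)
  expect_equal(agg$qc_flag, "ok")
  # noisy triplicate: drop the replicate whose removal minimises the SD
  agg2 <- aggregate_triplicates(make_ct(list("s1", "SFN", c(25.0, 25.1, 30.0))),
                                max_sd = 0.5)
  expect_equal(agg2$qc_flag, "rescued")
  expect_equal(agg2$mean_ct, 25.05)
  expect_equal(agg2$ct_sd, sd(c(25.0, 25.1)))
  expect_equal(agg2$n_replicates, 2L)
  # rescue disabled, or irreparable spread, flags high_sd
  agg3 <- aggregate_triplicates(make_ct(list("s1", "SFN", c(25.0, 25.1, 30.0))),
                                max_sd = 0.5, rescue = FALSE)
  expect_equal(agg3$qc_flag, "high_sd")
  agg4 <- aggregate_triplicates(make_ct(list("s1", "SFN", c(20, 25, 30))),
                                max_sd = 0.5)
  expect_equal(agg4$qc_flag, "high_sd")
  # fewer than two usable replicates is missing
  agg5 <- aggregate_triplicates(make_ct(list("s1", "SFN", c(25, NA, NA))))
  expect_equal(agg5$qc_flag, "missing")
  expect_true(is.na(agg5$mean_ct))
})

test_that("delta-Ct quantification is exact and invertible", {
  expect_equal(delta_ct(20, 20), 0)
  expect_equal(delta_ct(25, 20), 5)
  expect_equal(2^-delta_ct(25, 20), 0.03125)
  expect_equal(delta_ct(18, 20), -2)

  ct <- make_ct(list("s1", "SFN", c(25, 25, 25)),
                list("s1", "MT-ATP6", c(20, 20, 20)),
                list("s2", "SFN", c(18, 18, 18)),
                list("s2", "MT-ATP6", c(20, 20, 20)),
                list("s3", "SFN", c(24, 24, 24)),
                list("s3", "MT-ATP6", c(30, NA, NA)))
  expr <- relative_expression(ct, housekeeping = "MT-ATP6")
  e <- expr[match(c("s1", "s2"), expr$sample_id), ]
  expect_equal(e$delta_ct, c(5, -2))
  expect_equal(e$rel_expr, c(2^-5, 4))
  # the pipeline is exactly invertible on ok rows
  expect_equal(e$log2_rel_expr, -e$delta_ct)
  expect_equal(e$rel_expr, 2^(-e$delta_ct))
  # failed housekeeping leaves the sample without values
  e3 <- expr[expr$sample_id == "s3", ]
  expect_equal(e3$qc_flag, "missing_housekeeping")
  expect_true(is.na(e3$rel_expr))
  expect_error(relative_expression(ct, housekeeping = "GAPDH"), "absent")
})

test_that("group fold changes and Welch comparisons are exact", {
  ct <- do.call(make_ct, c(
    lapply(1:2, function(i) list(sprintf("h%d", i), "SFN", rep(25, 3))),
    lapply(1:2, function(i) list(sprintf("h%d", i), "MT-ATP6", rep(25, 3))),
    lapply(1:2, function(i) list(sprintf("t%d", i), "SFN",
                                 rep(25 - log2(15), 3))),
    lapply(1:2, function(i) list(sprintf("t%d", i), "MT-ATP6", rep(25, 3)))
  ))
  expr <- relative_expression(ct)
  meta <- make_meta(c("h1", "h2", "t1", "t2"),
                    rep(c("healthy", "tumour"), each = 2))
  fc <- group_fold_change(expr, meta, "SFN")
  expect_equal(fc$fold_change, 15, tolerance = 1e-10)
  # identical groups: unit fold change, zero statistic
  fc0 <- group_fold_change(expr, meta, "SFN", "healthy", "healthy")
  expect_equal(fc0$fold_change, 1)
  expect_equal(fc0$t_stat, 0)
  expect_error(group_fold_change(expr, meta, "SFN", "healthy", "high_risk"),
               ">= 2 usable")
  expect_error(group_fold_change(expr, meta, "SFN", "healthy", "banana"),
               "unknown group")
})

test_that("the Welch test equals its closed form and is swap-symmetric", {
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  ref <- bf_welch(a, b)
  ht <- t.test(b, a, var.equal = FALSE)
  expect_equal(unname(ht$statistic), ref$t, tolerance = 1e-12)
  expect_equal(unname(ht$parameter), ref$df, tolerance = 1e-12)
  expect_equal(ht$p.value, ref$p, tolerance = 1e-12)
  ht2 <- t.test(a, b, var.equal = FALSE)
  expect_equal(ht2$p.value, ht$p.value, tolerance = 1e-14)
})

test_that("cohort marker stats cover the contrasts with stars", {
  d <- sim_design(seed = 6, n_genes = 40, n_marker_genes = 4,
                  n_smoking_genes = 2)
  s <- simulate_ct(d, sim_params(marker_log2fc = 3, outlier_rate = 0))
  expr <- relative_expression(s$ct)
  stats <- cohort_marker_stats(expr, s$meta, c("MK0001", "MK0002"))
  expect_equal(nrow(stats), 8L)  # 2 genes x 4 contrasts
  tvh <- stats[stats$gene == "MK0001" & stats$group_a == "healthy" &
                 stats$group_b == "tumour", ]
  expect_lt(tvh$p_value, 0.05)
  expect_true(tvh$signif %in% c("*", "**"))
  expect_gt(tvh$fold_change, 1)
  # empty gene list gives an empty, well-formed table
  empty <- cohort_marker_stats(expr, s$meta, character(0))
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("gene", "fold_change", "p_value") %in% names(empty)))
})

test_that("female effect attenuation weakens the estimated effect", {
  est <- function(sex_want, seed) {
    d <- sim_design(seed = seed, n_genes = 40, n_marker_genes = 4,
                    n_smoking_genes = 2)
    s <- simulate_ct(d, sim_params(female_effect_attenuation = 0.3,
                                   outlier_rate = 0))
    expr <- relative_expression(s$ct)
    grp <- setNames(s$meta$group, s$meta$sample_id)
    sex <- setNames(s$meta$sex, s$meta$sample_id)
    dd <- expr[expr$gene == "MK0001" & sex[expr$sample_id] == sex_want, ]
    mean(dd$log2_rel_expr[grp[dd$sample_id] == "tumour"]) -
      mean(dd$log2_rel_expr[grp[dd$sample_id] == "healthy"])
  }
  male <- vapply(1:8, function(i) est("male", 100 + i), 0)
  female <- vapply(1:8, function(i) est("female", 100 + i), 0)
  expect_gt(mean(male), mean(female))
  expect_equal(mean(male), 3, tolerance = 0.6)
  expect_equal(mean(female), 0.9, tolerance = 0.6)
})
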