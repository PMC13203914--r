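test_that("one-way ANOVA reproduces the hand-worked three-group example", {
  groups <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(3, 4, 5))
  res <- one_way_anova(groups)
  expect_equal(res$ss_between, 6)
  expect_equal(res$ss_within, 6)
  expect_equal(res$f_stat, 3)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
  # closed form for F(2, 6): P(F > 3) = (1 + 3/3)^(-3) = 1/8
  expect_equal(res$p_value, 0.125, tolerance = 1e-12)
})

test_that("two-group ANOVA equals the squared pooled-variance t statistic", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      g1 <- rnorm(12, mean = 0)
      g2 <- rnorm(9, mean = 0.8)
    })
    res <- one_way_anova(list(a = g1, b = g2))
    tt <- t.test(g1, g2, var.equal = TRUE)
    expect_equal(res$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
    # the single pairwise raw p agrees too
    pw <- bonferroni_pairwise(list(a = g1, b = g2))
    expect_equal(pw$raw_p, res$p_value, tolerance = 1e-10)
    expect_equal(pw$adjusted_p, pw$raw_p)  # m = 1
  }
})

test_that("the sum-of-squares decomposition holds on arbitrary inputs", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      k <- sample(3:6, 1)
      groups <- lapply(seq_len(k), function(i) rnorm(sample(4:20, 1), mean = i / 2))
    })
    names(groups) <- paste0("g", seq_along(groups))
    res <- one_way_anova(groups)
    expect_equal(res$ss_between + res$ss_within, res$ss_total,
                 tolerance = 1e-9)
  }
})

test_that("identical constant groups degrade gracefully", {
  res <- one_way_anova(list(a = c(5, 5, 5), b = c(5, 5, 5)))
  expect_equal(res$f_stat, 0)
  expect_equal(res$p_value, 1)
  expect_true(all(res$assumption_flags$untestable))
  expect_error(one_way_anova(list(a = numeric(0), b = 1:3)), "empty")
  expect_error(one_way_anova(list(a = 1)), ">= 2 groups")
})

test_that("Bonferroni pairwise tables enumerate all pairs with monotone adjustment", {
  withr::with_seed(3, groups <- lapply(1:7, function(i) rnorm(10, mean = i / 4)))
  names(groups) <- treatment_levels()
  pw <- bonferroni_pairwise(groups)
  expect_equal(nrow(pw), 21)  # 7 * 6 / 2
  expect_true(all(pw$adjusted_p >= pw$raw_p))
  expect_equal(pw$adjusted_p, pmin(1, pw$raw_p * 21))
  expect_true(all(pw$tier[pw$adjusted_p <= 0.01] == "p<=0.01"))
  expect_true(all(pw$tier[pw$adjusted_p > 0.05] == "ns"))

  # identical groups -> nothing significant
  same <- lapply(1:3, function(i) c(1.2, 3.4, 2.2, 0.8, 1.9))
  names(same) <- c("a", "b", "c")
  pw0 <- bonferroni_pairwise(same)
  expect_true(all(pw0$adjusted_p == 1))
  expect_true(all(pw0$tier == "ns"))
})

test_that("pooled pairwise raw p-values match the reference routine", {
  withr::with_seed(8, groups <- lapply(1:4, function(i) rnorm(12, mean = i / 3)))
  names(groups) <- paste0("g", 1:4)
  pw <- bonferroni_pairwise(groups)
  values <- unlist(groups)
  g <- factor(rep(names(groups), lengths(groups)))
  ref <- pairwise.t.test(values, g, p.adjust.method = "none", pool.sd = TRUE)
  for (j in seq_len(nrow(pw))) {
    r <- ref$p.value[pw$group2[j], pw$group1[j]]
    expect_equal(pw$raw_p[j], unname(r), tolerance = 1e-10)
  }
})

test_that("a strongly shifted group reaches the strict tier on every contrast", {
  withr::with_seed(12, {
    groups <- lapply(1:4, function(i) rnorm(30))
    groups[[4]] <- groups[[4]] + 5
  })
  names(groups) <- paste0("g", 1:4)
  pw <- bonferroni_pairwise(groups)
  with4 <- pw$group1 == "g4" | pw$group2 == "g4"
  expect_true(all(pw$tier[with4] == "p<=0.01"))
})

test_that("assumption checks flag heteroscedasticity and tolerate degenerate groups", {
  withr::with_seed(5, {
    groups <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50, sd = sqrt(10)))
  })
  flags <- check_assumptions(groups)
  expect_lt(flags$levene_p, 0.05)
  expect_false(flags$homogeneity_ok)

  tiny <- check_assumptions(list(a = c(1, 1), b = rnorm(10)))
  expect_true(tiny$untestable["a"])

  # normal data rejects normality at roughly the nominal rate
  rejections <- 0L
  for (seed in 1:5) {
    withr::with_seed(seed, gs <- lapply(1:5, function(i) rnorm(50)))
    rejections <- rejections + sum(!check_assumptions(gs)$normality_ok)
  }
  expect_lte(rejections / 25, 0.2)
})

test_that("region analysis wires transforms, grouping and outputs together", {
  tab <- default_cohort(seed = 19)
  ra <- region_analysis(tab, "vol_mid", "treatment")
  expect_false(ra$transformed)
  expect_equal(ra$summaries$group, treatment_levels())
  expect_equal(ra$summaries$n, rep(30L, 7))
  expect_equal(nrow(ra$pairwise), 21)
  # percentages are arcsine-transformed before testing
  rp <- region_analysis(tab, "tm", "treatment")
  expect_true(rp$transformed)
  # summaries remain on the raw percent scale
  expect_gt(max(rp$summaries$mean), pi / 2)
  # donor grouping runs the by-stallion pathway
  rd <- region_analysis(tab, "vol_whole", "donor_id")
  expect_equal(nrow(rd$summaries), 10)
  expect_equal(nrow(rd$pairwise), 45)
  expect_error(region_analysis(tab, "volume_x", "treatment"), "unknown feature")
})
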