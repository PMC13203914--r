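test_that("fold assignment partitions the indices and balances classes", {
  # n = 10, k = 5 -> five folds of exactly two
  f <- make_folds(rep("x", 10), k = 5, stratified = FALSE, seed = 1)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 2))

  # 210 rows, 7 balanced classes, stratified -> 6 of each class per fold
  labels <- rep(treatment_levels(), each = 30)
  fs <- make_folds(labels, k = 5, stratified = TRUE, seed = 2)
  tab <- table(labels, fs)
  expect_true(all(tab == 6))

  # unbalanced class sizes still differ by at most one within each class
  lab2 <- rep(c("a", "b", "c"), times = c(7, 5, 11))
  f2 <- make_folds(lab2, k = 3, stratified = TRUE, seed = 3)
  per_class <- table(lab2, f2)
  expect_true(all(apply(per_class, 1, function(r) diff(range(r)) <= 1)))

  expect_identical(make_folds(labels, 5, TRUE, 9), make_folds(labels, 5, TRUE, 9))
  expect_error(make_folds(labels, k = 211, seed = 1), "exceeds")
})

test_that("nested CV is reproducible and keeps selections inside the grid", {
  tab <- default_cohort(seed = 6)
  cfg <- cv_config(pc_grid = c(2, 4, 6), seed = 11)
  r1 <- nested_cv_run(tab, "donor_id", cfg)
  r2 <- nested_cv_run(tab, "donor_id", cfg)
  expect_identical(r1$pooled_pred, r2$pooled_pred)
  expect_identical(r1$outer_accuracies, r2$outer_accuracies)
  expect_identical(r1$chosen_pcs, r2$chosen_pcs)
  expect_true(all(r1$chosen_pcs %in% cfg$pc_grid))
  expect_gte(r1$median_pcs, min(cfg$pc_grid))
  expect_lte(r1$median_pcs, max(cfg$pc_grid))
  expect_length(r1$outer_accuracies, 5)
  expect_length(r1$pooled_pred, nrow(tab))
  expect_equal(r1$mean_accuracy, mean(r1$outer_accuracies))
  expect_true(r1$mean_accuracy >= 0 && r1$mean_accuracy <= 1)
})

test_that("fixed-PC runs equal nested runs with a singleton grid exactly", {
  tab <- default_cohort(seed = 14)
  cfg <- cv_config(seed = 14)
  fixed <- fixed_pc_run(tab, "treatment", n_pcs = 5, config = cfg)
  single <- cv_config(pc_grid = 5, fixed_pcs = 5, seed = 14)
  nested <- nested_cv_run(tab, "treatment", single)
  expect_identical(fixed$result$pooled_pred, nested$pooled_pred)
  expect_identical(fixed$result$outer_accuracies, nested$outer_accuracies)
  expect_identical(fixed$result$chosen_pcs, nested$chosen_pcs)
  # the report's overall accuracy is the pooled confusion-matrix identity
  expect_equal(fixed$report$overall_accuracy,
               overall_accuracy(fixed$confusion))
  expect_equal(fixed$report$overall_accuracy, fixed$result$pooled_accuracy)
})

test_that("the inner loop prefers the smallest candidate on ties and in signal-on-PC1 data", {
  # class signal shared across all features: after z-scoring the common
  # class axis is by far the leading PC, and the separation is so wide that
  # every candidate reaches accuracy 1 -- the declared tie-break (smallest
  # PC count) must decide
  withr::with_seed(31, {
    n <- 60
    y <- rep(c("a", "b"), each = n / 2)
    shared <- ifelse(y == "a", -1, 1)
    x <- matrix(shared, n, 6) + matrix(rnorm(n * 6, sd = 0.15), n, 6)
  })
  cfg <- cv_config(pc_grid = c(2, 3, 4), fixed_pcs = 4, seed = 5)
  expect_equal(inner_select_pcs(x, y, cfg, seed = 5), 2)
  # singleton grid returns without any search
  cfg1 <- cv_config(pc_grid = 5, fixed_pcs = 5, seed = 5)
  expect_equal(inner_select_pcs(x, y, cfg1, seed = 5), 5)
})

test_that("a class absent from a training split raises a named fold error", {
  tab <- default_cohort(seed = 2)[1:22, ]  # donor #3 fully, donor #4 one row
  cfg <- cv_config(outer_k = 5, stratified = FALSE, pc_grid = 2, fixed_pcs = 2,
                   seed = 1)
  expect_error(nested_cv_run(tab, "donor_id", cfg), "absent from training")
})

test_that("pure-noise cohorts stay inside the chance band (leakage guard, quick)", {
  for (seed in 1:2) {
    nt <- null_cohort(synthetic_config(seed = seed))
    run <- fixed_pc_run(nt, "donor_id", 5, cv_config(seed = seed))
    acc <- run$result$pooled_accuracy
    band <- 4 * sqrt(0.1 * 0.9 / 210)
    expect_gte(acc, 0.1 - band)
    expect_lte(acc, 0.1 + band)
  }
})

test_that("the kNN and plug-in classifier slots run through the same engine", {
  tab <- default_cohort(seed = 4)
  rk <- fixed_pc_run(tab, "donor_id", 5, cv_config(classifier = "knn", seed = 4))
  expect_gt(rk$result$mean_accuracy, 0.3)  # well above 0.1 chance
  # plug-in slot: a nearest-centroid classifier
  centroid <- list(
    fit = function(scores, labels) {
      list(centers = do.call(rbind, lapply(split(as.data.frame(scores), labels),
                                           colMeans)))
    },
    predict = function(model, scores) {
      rownames(model$centers)[apply(scores, 1, function(r) {
        which.min(colSums((t(model$centers) - r)^2))
      })]
    }
  )
  rc <- fixed_pc_run(tab, "donor_id", 5, cv_config(classifier = centroid, seed = 4))
  expect_gt(rc$result$mean_accuracy, 0.3)
})

test_that("cv_config validates its arguments", {
  expect_error(cv_config(outer_k = 1), "outer_k")
  expect_error(cv_config(pc_grid = 0), "pc_grid")
  expect_error(cv_config(pc_grid = 2:10, fixed_pcs = 12), "fixed_pcs")
  expect_error(cv_config(classifier = "svm"), "classifier")
})
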