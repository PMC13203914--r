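test_that("PCA explained variances match an independent eigendecomposition", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- sample(6:20, 1)
      p <- sample(3:10, 1)
      x <- matrix(rnorm(n * p), n, p)
    })
    k <- min(n - 1, p)
    model <- pca_fit(x, k)
    oracle <- sort(eigen(cov(x), symmetric = TRUE)$values, decreasing = TRUE)
    expect_equal(model$explained_variance, oracle[seq_len(k)], tolerance = 1e-8)
    # orthonormal loadings
    g <- crossprod(model$components)
    expect_true(max(abs(g - diag(k))) < 1e-8)
    expect_true(all(diff(model$explained_variance) < 1e-12))
    expect_lte(sum(model$explained_fraction), 1 + 1e-12)
  }
})

test_that("rank-1 data puts all variance on the first component", {
  x1 <- c(1, 2, 3, 4, 5)
  x <- cbind(x1, 2 * x1)
  model <- pca_fit(x, 2)
  expect_equal(model$explained_fraction[1], 1, tolerance = 1e-10)
})

test_that("PCA projection reconstructs the centered matrix and honours shapes", {
  withr::with_seed(2, x <- matrix(rnorm(15 * 6), 15, 6))
  model <- pca_fit(x, 6)
  s <- pca_transform(model, x)
  expect_equal(apply(s, 2, var), model$explained_variance, tolerance = 1e-8)
  recon <- s %*% t(model$components)
  expect_equal(recon, sweep(x, 2, model$center), tolerance = 1e-8,
               ignore_attr = TRUE)
  # zero-variance input projects to zero scores
  const <- matrix(3, 4, 6)
  expect_true(all(abs(pca_transform(pca_fit(rbind(const, const), 2), const)) < 1e-12))
  expect_error(pca_fit(x, 7), "n_components")
  expect_error(pca_transform(model, matrix(0, 2, 5)), "feature count")
})

test_that("LDA discriminant scores match the brute-force closed form", {
  toy <- lda_toy()
  model <- lda_fit(toy$x, toy$y)
  got <- lda_discriminants(model, toy$x)
  want <- brute_force_lda_scores(toy$x, toy$y, toy$x)
  expect_equal(got, want, tolerance = 1e-10, ignore_attr = TRUE)
  expect_identical(lda_predict(model, toy$x), toy$y)  # separable toy
  expect_equal(sum(model$priors), 1)
  expect_equal(model$pooled_covariance, t(model$pooled_covariance))
})

test_that("well-separated clouds are classified perfectly in training", {
  cl <- separable_clouds()
  model <- lda_fit(cl$x, cl$y)
  expect_identical(lda_predict(model, cl$x), cl$y)
})

test_that("LDA falls back to priors on identical classes and breaks ties by label order", {
  # identical class means and scatter, unbalanced priors -> majority class wins
  x <- rbind(c(0, 0), c(1, 1), c(0, 0), c(1, 1), c(0, 0), c(1, 1))
  y <- c("a", "a", "a", "a", "b", "b")
  model <- lda_fit(x, y)
  expect_true(all(lda_predict(model, x) == "a"))

  # symmetric two-class toy, equal priors: the midpoint is equidistant and
  # must resolve to the first label in class order
  xs <- rbind(c(-1, 0), c(-2, 0), c(1, 0), c(2, 0))
  ys <- c("a", "a", "b", "b")
  ms <- lda_fit(xs, ys)
  expect_identical(lda_predict(ms, matrix(c(0, 0), 1)), "a")
})

test_that("LDA reduces to nearest class mean under identity covariance", {
  # spherical classes with equal sizes: decision = nearest centroid
  withr::with_seed(7, {
    centers <- matrix(c(0, 0, 6, 0, 0, 6), ncol = 2, byrow = TRUE)
    x <- do.call(rbind, lapply(1:3, function(i) {
      sweep(matrix(rnorm(30 * 2), 30, 2), 2, centers[i, ], "+")
    }))
  })
  y <- rep(c("a", "b", "c"), each = 30)
  model <- lda_fit(x, y)
  pred <- lda_predict(model, x)
  centroid_pred <- sapply(seq_len(nrow(x)), function(i) {
    d <- rowSums((sweep(model$class_means, 2, x[i, ]))^2)
    model$class_labels[which.min(d)]
  })
  expect_gt(mean(pred == centroid_pred), 0.97)
})

test_that("LDA fit is invariant to training row order", {
  toy <- lda_toy()
  perm <- c(7, 3, 12, 1, 9, 5, 11, 2, 8, 4, 10, 6)
  m1 <- lda_fit(toy$x, toy$y)
  m2 <- lda_fit(toy$x[perm, ], toy$y[perm])
  expect_equal(m1$class_means, m2$class_means)
  expect_equal(m1$pooled_covariance, m2$pooled_covariance)
  expect_equal(m1$priors, m2$priors)
})

test_that("LDA agrees with an established reference implementation", {
  skip_if_not_installed("MASS")
  withr::with_seed(13, {
    x <- rbind(matrix(rnorm(40, mean = 0), ncol = 2),
               matrix(rnorm(40, mean = 1.5), ncol = 2),
               matrix(rnorm(20, mean = c(4, -2)), ncol = 2))
  })
  y <- rep(c("a", "b", "c"), times = c(20, 20, 10))
  ours <- lda_predict(lda_fit(x, y), x)
  ref <- as.character(stats::predict(MASS::lda(x, grouping = y))$class)
  expect_gt(mean(ours == ref), 0.97)
})

test_that("LDA input contracts are enforced", {
  expect_error(lda_fit(matrix(1:4, 2), c("a", "a")), "2 classes")
  expect_error(lda_fit(matrix(1:4, 2), c("a")), "lengths differ")
})

test_that("kNN matches an exhaustive distance sort on a hand example", {
  train <- matrix(c(0, 0, 1, 0, 2, 0, 10, 0, 11, 0), ncol = 2, byrow = TRUE)
  labels <- c("a", "a", "b", "b", "b")
  # test point at (0.5, 0): distances 0.5, 0.5, 1.5, 9.5, 10.5
  # k = 3 neighbours -> {a, a, b} -> "a"
  expect_identical(knn_predict(train, labels, matrix(c(0.5, 0), 1), k = 3), "a")
  # k = 5 -> 2 a's vs 3 b's -> "b"
  expect_identical(knn_predict(train, labels, matrix(c(0.5, 0), 1), k = 5), "b")
  # k = 1 on the training set itself: zero-distance self neighbour
  expect_identical(knn_predict(train, labels, train, k = 1), labels)
  # k = n: constant majority vote
  expect_true(all(knn_predict(train, labels, train, k = 5) == "b"))
  # vote tie at k = 2 ({a, a} vs ... ) construct explicit tie:
  # neighbours one a at 0.5 and one b at 1.5 -> tie broken by mean distance
  expect_identical(knn_predict(train[c(2, 3), ], c("a", "b"),
                               matrix(c(1.5, 0), 1), k = 2), "a")
  expect_error(knn_predict(train, labels, train, k = 6), "k must lie")
})
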