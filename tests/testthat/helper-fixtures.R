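# Shared fixtures: small cohorts and deterministic toy data built in code.

default_cohort <- function(seed = 1) {
  generate_cohort(synthetic_config(seed = seed))
}

# A noiseless profile: only the freeze shift survives, so every value is an
# exact deterministic sum.
noiseless_profile <- function() {
  base <- default_effect_profile()
  zero <- stats::setNames(numeric(14), feature_columns())
  effect_profile(
    baseline_means = base$baseline_means,
    donor_sd = zero,
    freeze_shift = base$freeze_shift,
    antiox_shift = NULL,
    noise_sd = zero
  )
}

# Two well-separated spherical Gaussian clouds in 2-D.
separable_clouds <- function(n = 20, seed = 42) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n * 2, mean = -5), ncol = 2),
               matrix(rnorm(n * 2, mean = 5), ncol = 2))
  })
  list(x = x, y = rep(c("a", "b"), each = n))
}

# 12-point, 3-class toy in 2-D with unequal class sizes (so priors matter).
lda_toy <- function() {
  x <- rbind(
    c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0.5, 0.5),   # class a (5)
    c(4, 0), c(5, 0), c(4, 1), c(5, 1),                 # class b (4)
    c(0, 4), c(1, 4), c(0.5, 5)                         # class c (3)
  )
  list(x = x, y = rep(c("a", "b", "c"), times = c(5, 4, 3)))
}

# Brute-force LDA oracle: pooled covariance and the closed-form discriminant
# evaluated point by point, independent of the package's linear-algebra path.
brute_force_lda_scores <- function(x, y, newdata, ridge = 1e-6) {
  classes <- sort(unique(y))
  p <- ncol(x)
  n <- nrow(x)
  ssw <- matrix(0, p, p)
  means <- list()
  for (cl in classes) {
    rows <- x[y == cl, , drop = FALSE]
    mu <- colMeans(rows)
    means[[cl]] <- mu
    for (i in seq_len(nrow(rows))) {
      d <- rows[i, ] - mu
      ssw <- ssw + outer(d, d)
    }
  }
  sigma <- ssw / (n - length(classes))
  sigma <- sigma + diag(ridge * sum(diag(sigma)) / p, p)
  out <- matrix(NA_real_, nrow(newdata), length(classes),
                dimnames = list(NULL, classes))
  for (cl in classes) {
    mu <- means[[cl]]
    prior <- mean(y == cl)
    for (i in seq_len(nrow(newdata))) {
      xi <- newdata[i, ]
      out[i, cl] <- sum(xi * solve(sigma, mu)) -
        0.5 * sum(mu * solve(sigma, mu)) + log(prior)
    }
  }
  out
}
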