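#' Principal component analysis by singular value decomposition
#'
#' Fits PCA on a (typically z-scored) observations-by-features matrix via
#' SVD of the column-centered matrix. Components carry a deterministic sign
#' convention: the loading coefficient of largest magnitude in each component
#' is positive. Explained variances use the sample (n - 1) convention and
#' equal the leading eigenvalues of the sample covariance matrix.
#'
#' @param x numeric matrix, observations by features.
#' @param n_components number of components to retain; must satisfy
#'   `n_components <= min(nrow(x) - 1, ncol(x))`.
#' @return an object of class `"pca_model"` with elements `components`
#'   (features x n_components orthonormal loadings), `center`,
#'   `explained_variance` and `explained_fraction`.
#' @export
pca_fit <- function(x, n_components) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n_components < 1 || n_components > min(n - 1, p)) {
    stop("pca_fit: n_components must lie in [1, min(rows - 1, features)] = [1, ",
         min(n - 1, p), "]", call. = FALSE)
  }
  center <- colMeans(x)
  xc <- sweep(x, 2, center, "-")
  sv <- svd(xc)
  comp <- sv$v[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-magnitude loading positive (first on ties)
  for (j in seq_len(n_components)) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  ev_all <- sv$d^2 / (n - 1)
  total <- sum(ev_all)
  ev <- ev_all[seq_len(n_components)]
  structure(
    list(components = comp, center = center,
         explained_variance = ev,
         explained_fraction = if (total > 0) ev / total else rep(0, n_components)),
    class = "pca_model"
  )
}

#' Project observations onto fitted principal components
#'
#' @param model a `"pca_model"` from [pca_fit()].
#' @param x matrix with the same feature count as the fit set; may contain
#'   held-out rows (no refit occurs).
#' @return score matrix, observations by components.
#' @export
pca_transform <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$center)) {
    stop("pca_transform: feature count (", ncol(x),
         ") does not match the fitted model (", length(model$center), ")",
         call. = FALSE)
  }
  sweep(x, 2, model$center, "-") %*% model$components
}

#' Fit a multiclass linear discriminant model
#'
#' Gaussian classes with a shared (pooled) within-class covariance
#' `Sigma = sum_c (n_c - 1) S_c / (N - C)`, regularized by a scale-aware
#' ridge `lambda * tr(Sigma) / p * I` (default `lambda = 1e-6`) so small
#' training folds cannot produce a singular covariance. Priors are the
#' empirical class frequencies.
#'
#' @param scores numeric matrix, observations by dimensions (typically PCA
#'   scores).
#' @param labels class labels, one per row; at least two classes, each with
#'   at least one row.
#' @param ridge ridge multiplier `lambda`.
#' @return an object of class `"lda_model"` with `class_labels`,
#'   `class_means`, `pooled_covariance` (ridge included), `priors`, `ridge`.
#' @export
lda_fit <- function(scores, labels, ridge = 1e-6) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  if (nrow(scores) != length(labels)) {
    stop("lda_fit: scores and labels lengths differ", call. = FALSE)
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    stop("lda_fit: need at least 2 classes", call. = FALSE)
  }
  p <- ncol(scores)
  n <- nrow(scores)
  k <- length(classes)
  counts <- table(factor(labels, levels = classes))
  if (any(counts == 0)) {
    stop("lda_fit: class with 0 training rows: ",
         paste(classes[counts == 0], collapse = ", "), call. = FALSE)
  }
  means <- matrix(0, nrow = k, ncol = p, dimnames = list(classes, NULL))
  ssw <- matrix(0, nrow = p, ncol = p)
  for (c_i in seq_along(classes)) {
    rows <- scores[labels == classes[c_i], , drop = FALSE]
    means[c_i, ] <- colMeans(rows)
    if (nrow(rows) > 1) {
      d <- sweep(rows, 2, means[c_i, ], "-")
      ssw <- ssw + crossprod(d)
    }
  }
  if (n - k < 1) {
    stop("lda_fit: not enough observations to estimate a pooled covariance",
         call. = FALSE)
  }
  sigma <- ssw / (n - k)
  sigma <- sigma + diag(ridge * sum(diag(sigma)) / p, p)
  inv_sigma <- solve(sigma)
  structure(
    list(class_labels = classes, class_means = means,
         pooled_covariance = sigma, inv_covariance = inv_sigma,
         priors = as.numeric(counts) / n, ridge = ridge),
    class = "lda_model"
  )
}

#' Linear discriminant scores
#'
#' Evaluates the closed-form discriminant
#' `delta_c(x) = x' Sigma^-1 mu_c - mu_c' Sigma^-1 mu_c / 2 + log pi_c`
#' for every class.
#'
#' @param model an `"lda_model"`.
#' @param scores matrix of observations in the model's space.
#' @return matrix of discriminant scores, observations by classes.
#' @export
lda_discriminants <- function(model, scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != ncol(model$class_means)) {
    stop("lda_discriminants: dimension mismatch", call. = FALSE)
  }
  m_inv <- model$class_means %*% model$inv_covariance    # k x p
  lin <- scores %*% t(m_inv)                             # n x k
  const <- -0.5 * rowSums(m_inv * model$class_means) + log(model$priors)
  out <- sweep(lin, 2, const, "+")
  colnames(out) <- model$class_labels
  out
}

#' Predict class labels with a fitted LDA model
#'
#' Argmax over discriminant scores; exact ties break toward the earlier
#' class in `class_labels` order.
#'
#' @inheritParams lda_discriminants
#' @return character vector of predicted labels.
#' @export
lda_predict <- function(model, scores) {
  d <- lda_discriminants(model, scores)
  model$class_labels[max.col(d, ties.method = "first")]
}

#' k-nearest-neighbour classification
#'
#' Majority vote among the `k` Euclidean nearest training neighbours.
#' Vote ties break toward the tied class with the smallest mean neighbour
#' distance, then by class-label order.
#'
#' @param train_scores,train_labels training observations and their labels.
#' @param test_scores observations to classify.
#' @param k neighbourhood size (default 5); must not exceed the number of
#'   training rows.
#' @return character vector of predicted labels.
#' @export
knn_predict <- function(train_scores, train_labels, test_scores, k = 5) {
  train_scores <- as.matrix(train_scores)
  test_scores <- as.matrix(test_scores)
  train_labels <- as.character(train_labels)
  n <- nrow(train_scores)
  if (k < 1 || k > n) {
    stop("knn_predict: k must lie in [1, number of training rows]", call. = FALSE)
  }
  out <- character(nrow(test_scores))
  for (i in seq_len(nrow(test_scores))) {
    d2 <- colSums((t(train_scores) - test_scores[i, ])^2)
    nb <- order(d2)[seq_len(k)]
    votes <- table(train_labels[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      mean_d <- vapply(top, function(lb) {
        mean(sqrt(d2[nb][train_labels[nb] == lb]))
      }, numeric(1))
      top <- top[order(mean_d, top)]
    }
    out[i] <- top[1]
  }
  out
}
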