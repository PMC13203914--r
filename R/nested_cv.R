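#' Cross-validation configuration
#'
#' @param outer_k,inner_k outer and inner fold counts (default 5 and 5).
#' @param pc_grid candidate principal-component counts searched by the inner
#'   loop (default 2:15).
#' @param fixed_pcs PC count used by [fixed_pc_run()] (default 5).
#' @param classifier `"lda"` (default), `"knn"`, or a plug-in: a list with
#'   functions `fit(scores, labels)` and `predict(model, scores)`.
#' @param knn_k neighbourhood size when `classifier = "knn"` (default 5).
#' @param stratified stratify folds by the target label (default `TRUE`).
#'   With 10 donor classes and modest n, unstratified folds can drop a class
#'   from a training split entirely, which makes the fit undefined.
#' @param include_age include donor age among the modelling features
#'   (default `TRUE`; set `FALSE` to study age-driven leakage into donor
#'   classification).
#' @param ridge LDA covariance ridge multiplier.
#' @param seed master seed; all fold assignments and inner-loop seeds derive
#'   from it deterministically.
#' @return an object of class `"cv_config"`.
#' @export
cv_config <- function(outer_k = 5, inner_k = 5, pc_grid = 2:15, fixed_pcs = 5,
                      classifier = "lda", knn_k = 5, stratified = TRUE,
                      include_age = TRUE, ridge = 1e-6, seed = 1L) {
  if (outer_k < 2 || inner_k < 2) {
    stop("cv_config: outer_k and inner_k must both be >= 2", call. = FALSE)
  }
  pc_grid <- sort(unique(as.integer(pc_grid)))
  if (any(pc_grid < 1)) stop("cv_config: pc_grid entries must be >= 1", call. = FALSE)
  if (!is.null(fixed_pcs) &&
      (fixed_pcs < min(pc_grid) || fixed_pcs > max(pc_grid))) {
    stop("cv_config: fixed_pcs must lie within the pc_grid bounds", call. = FALSE)
  }
  if (!is.list(classifier) && !classifier %in% c("lda", "knn")) {
    stop("cv_config: classifier must be 'lda', 'knn' or a fit/predict list",
         call. = FALSE)
  }
  structure(
    list(outer_k = outer_k, inner_k = inner_k, pc_grid = pc_grid,
         fixed_pcs = fixed_pcs, classifier = classifier, knn_k = knn_k,
         stratified = isTRUE(stratified), include_age = isTRUE(include_age),
         ridge = ridge, seed = as.integer(seed)),
    class = "cv_config"
  )
}

#' Seeded k-fold assignment, optionally stratified
#'
#' Stratified assignment shuffles each class and deals its members across
#' folds round-robin (continuing the dealing cursor across classes), so fold
#' sizes within every class differ by at most one and overall fold sizes
#' stay balanced.
#'
#' @param labels target labels, one per observation.
#' @param k number of folds; at most the number of observations.
#' @param stratified balance class counts across folds (default `TRUE`).
#' @param seed RNG seed for the shuffle.
#' @return integer vector of fold indices in 1..k, one per observation.
#' @export
make_folds <- function(labels, k, stratified = TRUE, seed = 1L) {
  n <- length(labels)
  if (k > n) stop("make_folds: k exceeds the number of observations", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    folds <- integer(n)
    if (stratified) {
      cursor <- 0L
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- ((cursor + seq_along(idx) - 1L) %% k) + 1L
        cursor <- (cursor + length(idx)) %% k
      }
    } else {
      folds <- sample(rep(seq_len(k), length.out = n))
    }
  })
  folds
}

# Extract the modelling matrix and label vector from a feature table.
model_matrix_labels <- function(table, label_column, include_age = TRUE) {
  table <- validate_feature_table(table)
  if (!label_column %in% c("donor_id", "treatment")) {
    stop("label_column must be 'donor_id' or 'treatment'", call. = FALSE)
  }
  cols <- if (include_age) model_columns() else feature_columns()
  list(x = as.matrix(table[, cols]), y = as.character(table[[label_column]]))
}

# One CV pass at a fixed PC count: per fold, z-score and PCA are fitted on
# the training rows only (leakage contract), then the classifier predicts the
# held-out rows. Returns per-fold accuracies and pooled predictions in the
# original row order.
cv_pass <- function(x, y, folds, n_pcs, config) {
  k <- max(folds)
  pooled_pred <- character(length(y))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    te <- folds == f
    one <- cv_pass_single(x, y, !te, te, n_pcs, config, fold_id = f)
    pooled_pred[te] <- one$pred
    fold_acc[f] <- one$acc
  }
  list(fold_acc = fold_acc, pooled_pred = pooled_pred)
}

#' Inner-loop selection of the principal-component count
#'
#' Runs `inner_k`-fold cross-validation inside a training set for every
#' candidate PC count in the grid (z-score and PCA refitted on each
#' inner-training split) and returns the candidate with the highest mean
#' inner accuracy; ties break toward the smallest candidate. Candidates
#' exceeding the rank available in the smallest inner-training split are
#' dropped. A singleton grid is returned without running any search.
#'
#' @param x numeric modelling matrix of the training rows.
#' @param y their labels.
#' @param config a [cv_config()]; uses `pc_grid`, `inner_k`, `stratified`,
#'   and the classifier settings.
#' @param seed seed for the inner fold assignment.
#' @return the selected PC count (integer).
#' @export
inner_select_pcs <- function(x, y, config, seed = config$seed) {
  grid <- config$pc_grid
  if (length(grid) == 1) return(grid)
  folds <- make_folds(y, config$inner_k, config$stratified, seed)
  min_train <- min(vapply(seq_len(config$inner_k),
                          function(f) sum(folds != f), integer(1)))
  feasible <- grid[grid <= min(min_train - 1L, ncol(x))]
  if (length(feasible) == 0) {
    stop("inner_select_pcs: no candidate PC count is feasible for the ",
         "inner-training rank", call. = FALSE)
  }
  mean_acc <- vapply(feasible, function(npc) {
    mean(cv_pass(x, y, folds, npc, config)$fold_acc)
  }, numeric(1))
  feasible[which.max(mean_acc)]  # first max = smallest candidate on ties
}

# Matrix-level nested CV; `nested_cv_run` and the permutation loop both call
# this. Outer fold seeds and per-fold inner seeds derive from config$seed.
nested_cv_matrix <- function(x, y, config) {
  seeds <- withr::with_seed(config$seed,
                            sample.int(.Machine$integer.max, config$outer_k + 1L))
  folds <- make_folds(y, config$outer_k, config$stratified, seeds[1])
  pooled_pred <- character(length(y))
  fold_acc <- numeric(config$outer_k)
  chosen <- integer(config$outer_k)
  for (f in seq_len(config$outer_k)) {
    te <- folds == f
    tr <- !te
    npc <- inner_select_pcs(x[tr, , drop = FALSE], y[tr], config,
                            seed = seeds[f + 1])
    chosen[f] <- npc
    one <- cv_pass_single(x, y, tr, te, npc, config, fold_id = f)
    pooled_pred[te] <- one$pred
    fold_acc[f] <- one$acc
  }
  structure(
    list(outer_accuracies = fold_acc,
         mean_accuracy = mean(fold_acc),
         chosen_pcs = chosen,
         median_pcs = stats::median(chosen),
         pooled_true = y,
         pooled_pred = pooled_pred,
         pooled_accuracy = mean(pooled_pred == y),
         fold_assignments = folds,
         config = config),
    class = "nested_cv_result"
  )
}

# Fit-and-predict for one explicit train/test split at a fixed PC count.
cv_pass_single <- function(x, y, tr, te, n_pcs, config, fold_id = NA) {
  y_tr <- y[tr]
  missing_class <- setdiff(unique(y), unique(y_tr))
  if (length(missing_class) > 0) {
    stop("outer fold ", fold_id, ": class absent from training split: ",
         paste(missing_class, collapse = ", "), call. = FALSE)
  }
  npc <- min(n_pcs, sum(tr) - 1L, ncol(x))
  std <- zscore_fit(x[tr, , drop = FALSE])
  z_tr <- zscore_apply(std, x[tr, , drop = FALSE])
  z_te <- zscore_apply(std, x[te, , drop = FALSE])
  pca <- pca_fit(z_tr, npc)
  s_tr <- pca_transform(pca, z_tr)
  s_te <- pca_transform(pca, z_te)
  pred <- if (is.list(config$classifier)) {
    m <- config$classifier$fit(s_tr, y_tr)
    as.character(config$classifier$predict(m, s_te))
  } else if (config$classifier == "knn") {
    knn_predict(s_tr, y_tr, s_te, k = min(config$knn_k, nrow(s_tr)))
  } else {
    lda_predict(lda_fit(s_tr, y_tr, ridge = config$ridge), s_te)
  }
  list(pred = pred, acc = mean(pred == y[te]))
}

#' Nested cross-validated classification of a feature table
#'
#' The outer folds estimate generalization accuracy; each outer fold's inner
#' loop (run only on that fold's training rows) selects the PC count from
#' `config$pc_grid`. Per outer fold, z-scoring and PCA are fitted on the
#' outer-training rows only and never see the held-out rows. The headline
#' `mean_accuracy` is the mean of the outer-fold accuracies; the pooled
#' out-of-fold predictions (and `pooled_accuracy`) are also returned -- with
#' equal fold sizes the two aggregations coincide.
#'
#' @param table a validated feature table.
#' @param label_column classification target: `"donor_id"` or `"treatment"`.
#' @param config a [cv_config()].
#' @return an object of class `"nested_cv_result"` with per-fold accuracies,
#'   mean accuracy, selected PC counts and their median, and pooled true /
#'   predicted labels in row order.
#' @export
nested_cv_run <- function(table, label_column, config = cv_config()) {
  ml <- model_matrix_labels(table, label_column, config$include_age)
  res <- nested_cv_matrix(ml$x, ml$y, config)
  res$label_column <- label_column
  res
}

#' Fixed-PC nested cross-validation with a classification report
#'
#' Identical to [nested_cv_run()] with the inner search replaced by a fixed
#' PC count (implemented as a singleton grid, so the equivalence is exact).
#' The pooled out-of-fold predictions feed a confusion matrix and per-class
#' metrics -- the pathway producing class-wise performance panels.
#'
#' @inheritParams nested_cv_run
#' @param n_pcs the fixed PC count (default 5).
#' @return a list with `result` (the `"nested_cv_result"`), `confusion`
#'   (a `"confusion_matrix"` over pooled predictions) and `report`
#'   (a `"classification_report"`).
#' @export
fixed_pc_run <- function(table, label_column, n_pcs = 5, config = cv_config()) {
  cfg <- config
  cfg$pc_grid <- as.integer(n_pcs)
  cfg$fixed_pcs <- as.integer(n_pcs)
  res <- nested_cv_run(table, label_column, cfg)
  cm <- confusion_matrix(res$pooled_true, res$pooled_pred,
                         class_order = sort(unique(res$pooled_true)))
  list(result = res, confusion = cm, report = per_class_metrics(cm))
}
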