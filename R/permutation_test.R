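#' Uniform random permutation of a label multiset
#'
#' Class counts are conserved exactly; only the assignment of labels to rows
#' changes. Consumes the current RNG stream (seed handled by the caller).
#'
#' @param labels non-empty label vector.
#' @return the shuffled labels.
#' @export
permute_labels <- function(labels) {
  if (length(labels) == 0) stop("permute_labels: empty labels", call. = FALSE)
  labels[sample.int(length(labels))]
}

#' Permutation p-value for an observed accuracy
#'
#' The proportion of null accuracies equal to or greater than the observed
#' value (ties count toward the tail). The bias-corrected variant
#' `(m + 1) / (B + 1)` is available behind `corrected`.
#'
#' @param observed observed accuracy.
#' @param null_accuracies non-empty vector of accuracies under shuffled
#'   labels.
#' @param corrected use the add-one correction (default `FALSE`).
#' @return a fraction in \[0, 1\].
#' @export
permutation_pvalue <- function(observed, null_accuracies, corrected = FALSE) {
  b <- length(null_accuracies)
  if (b == 0) stop("permutation_pvalue: empty null distribution", call. = FALSE)
  m <- sum(null_accuracies >= observed)
  if (corrected) (m + 1) / (b + 1) else m / b
}

#' Label-permutation significance test of the classification pipeline
#'
#' The observed accuracy comes from the unpermuted fixed-PC run. Each of the
#' `b` permutations shuffles the class labels, re-draws the fold assignment,
#' and reruns the entire fixed-PC pipeline (z-score, PCA and classifier all
#' refitted) under a per-permutation seed derived from the master seed. The
#' resulting null distribution of accuracies represents performance expected
#' by chance; the p-value is the proportion of null accuracies at or above
#' the observed one. Accuracies are mean-of-outer-folds throughout.
#'
#' The inner PC search is not rerun inside permutations by default (the
#' fixed-PC pipeline is what is permuted); set `nested = TRUE` to permute
#' the full nested search instead.
#'
#' @param table a validated feature table.
#' @param label_column `"donor_id"` or `"treatment"`.
#' @param config a [cv_config()].
#' @param b number of permutations (default 1000).
#' @param n_pcs fixed PC count for the permuted pipeline (default 5).
#' @param seed master seed; defaults to `config$seed`.
#' @param corrected passed to [permutation_pvalue()].
#' @param nested permute the full nested search (default `FALSE`).
#' @return an object of class `"permutation_result"` with
#'   `observed_accuracy`, `null_accuracies`, `p_value`, `b`, `seed`.
#' @export
run_permutation_test <- function(table, label_column, config = cv_config(),
                                 b = 1000, n_pcs = 5, seed = config$seed,
                                 corrected = FALSE, nested = FALSE) {
  if (b < 1) stop("run_permutation_test: b must be >= 1", call. = FALSE)
  ml <- model_matrix_labels(table, label_column, config$include_age)
  cfg <- config
  if (!nested) {
    cfg$pc_grid <- as.integer(n_pcs)
    cfg$fixed_pcs <- as.integer(n_pcs)
  }
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max, 2L * b + 1L))
  cfg$seed <- seeds[1]
  observed <- nested_cv_matrix(ml$x, ml$y, cfg)$mean_accuracy
  null_acc <- numeric(b)
  for (i in seq_len(b)) {
    y_perm <- withr::with_seed(seeds[2L * i], permute_labels(ml$y))
    cfg$seed <- seeds[2L * i + 1L]
    null_acc[i] <- tryCatch(
      nested_cv_matrix(ml$x, y_perm, cfg)$mean_accuracy,
      error = function(e) {
        stop("run_permutation_test: pipeline failed at permutation ", i, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  structure(
    list(observed_accuracy = observed, null_accuracies = null_acc,
         p_value = permutation_pvalue(observed, null_acc, corrected),
         b = as.integer(b), seed = as.integer(seed), corrected = corrected,
         label_column = label_column),
    class = "permutation_result"
  )
}
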