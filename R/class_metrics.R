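#' Multiclass confusion matrix
#'
#' Rows index the true class, columns the predicted class:
#' `counts[i, j]` is the number of observations of true class `i` predicted
#' as class `j`.
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param class_order ordered class labels; defaults to the sorted union of
#'   the observed labels. Labels outside it are an error.
#' @return an object of class `"confusion_matrix"` with `class_labels` and
#'   the integer `counts` matrix.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, class_order = NULL) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stop("confusion_matrix: label vectors have different lengths", call. = FALSE)
  }
  if (is.null(class_order)) {
    class_order <- sort(unique(c(true_labels, predicted_labels)))
  }
  unknown <- setdiff(unique(c(true_labels, predicted_labels)), class_order)
  if (length(unknown) > 0) {
    stop("confusion_matrix: label(s) not in class_order: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(true_labels, levels = class_order),
                  factor(predicted_labels, levels = class_order))
  counts <- matrix(as.integer(counts), nrow = length(class_order),
                   dimnames = list(true = class_order, predicted = class_order))
  structure(list(class_labels = class_order, counts = counts),
            class = "confusion_matrix")
}

#' Per-class classification metrics
#'
#' For each class `c`, with TP, FN, FP, TN read off the confusion matrix:
#' sensitivity `TP / (TP + FN)`, specificity `TN / (TN + FP)`, precision
#' `TP / (TP + FP)`, and the F1 score, the harmonic mean of precision and
#' sensitivity. A zero denominator yields `NA` (undefined), never a silent
#' zero, so degenerate folds cannot corrupt averages. Overall accuracy is
#' the trace over the total.
#'
#' @param cm a `"confusion_matrix"`.
#' @return an object of class `"classification_report"`: a tibble
#'   `per_class` (class, sensitivity, specificity, precision, f1) plus
#'   `overall_accuracy`.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  counts <- cm$counts
  total <- sum(counts)
  if (total == 0) stop("per_class_metrics: empty confusion matrix", call. = FALSE)
  tp <- diag(counts)
  fn <- rowSums(counts) - tp
  fp <- colSums(counts) - tp
  tn <- total - tp - fn - fp
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- ifelse(!is.na(prec) & !is.na(sens) & (prec + sens) > 0,
               2 * prec * sens / (prec + sens), NA_real_)
  structure(
    list(
      per_class = tibble::tibble(
        class = cm$class_labels,
        sensitivity = as.numeric(sens),
        specificity = as.numeric(spec),
        precision = as.numeric(prec),
        f1 = as.numeric(f1)
      ),
      overall_accuracy = sum(tp) / total
    ),
    class = "classification_report"
  )
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm a `"confusion_matrix"` with at least one scored observation.
#' @return trace / total, a fraction in \[0, 1\].
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm$counts)
  if (total == 0) stop("overall_accuracy: empty confusion matrix", call. = FALSE)
  sum(diag(cm$counts)) / total
}

#' Write a per-class metrics table to CSV
#'
#' One row per class with sensitivity, specificity, precision and F1,
#' mirroring the layout of a class-wise performance panel.
#'
#' @param report a `"classification_report"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "classification_report"))
  utils::write.csv(as.data.frame(report$per_class), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
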