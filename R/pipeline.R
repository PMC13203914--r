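#' Render a confusion matrix as a heatmap image
#'
#' Diagonal (correct) cells are shaded blue and off-diagonal (error) cells
#' red, darker for higher counts, with the count printed in each cell.
#'
#' @param cm a `"confusion_matrix"`.
#' @param path output image path (extension decides the device, e.g. `.png`).
#' @param title optional plot title.
#' @return `path`, invisibly.
#' @export
render_confusion_heatmap <- function(cm, path, title = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  lv <- cm$class_labels
  df <- expand.grid(true = lv, predicted = lv, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df$count <- as.vector(cm$counts[cbind(match(df$true, lv), match(df$predicted, lv))])
  df$diag <- df$true == df$predicted
  mx <- max(df$count, 1)
  shade <- df$count / mx
  blue <- grDevices::colorRamp(c("#FFFFFF", "#08306B"))
  red <- grDevices::colorRamp(c("#FFFFFF", "#A50F15"))
  rgb_of <- function(ramp, s) grDevices::rgb(ramp(s), maxColorValue = 255)
  df$fill <- ifelse(df$diag, vapply(shade, function(s) rgb_of(blue, s), ""),
                    vapply(shade, function(s) rgb_of(red, s), ""))
  df$true <- factor(df$true, levels = rev(lv))
  df$predicted <- factor(df$predicted, levels = lv)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$fill), color = "grey60") +
    ggplot2::scale_fill_identity() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count),
                       color = ifelse(shade > 0.6, "white", "black"), size = 3) +
    ggplot2::labs(x = "Predicted class", y = "True class", title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  ggplot2::ggsave(path, p, width = 2 + 0.5 * length(lv),
                  height = 1.5 + 0.5 * length(lv), dpi = 150)
  invisible(path)
}

#' Render region-volume box plots by group
#'
#' @param table a validated feature table.
#' @param feature feature column to plot.
#' @param grouping `"treatment"` or `"donor_id"`.
#' @param path output image path.
#' @return `path`, invisibly.
#' @export
render_volume_boxplot <- function(table, feature, grouping, path) {
  table <- validate_feature_table(table)
  lv <- if (grouping == "treatment") treatment_levels() else unique(table[[grouping]])
  df <- data.frame(group = factor(table[[grouping]], levels = lv),
                   value = table[[feature]])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                        fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = grouping, y = feature) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  ggplot2::ggsave(path, p, width = 7, height = 4, dpi = 150)
  invisible(path)
}

json_write <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

result_to_list <- function(res) {
  list(
    label_column = res$label_column,
    outer_accuracies = res$outer_accuracies,
    mean_accuracy = res$mean_accuracy,
    pooled_accuracy = res$pooled_accuracy,
    chosen_pcs = res$chosen_pcs,
    median_pcs = res$median_pcs,
    pooled_true = res$pooled_true,
    pooled_pred = res$pooled_pred
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates the complete workflow on either a synthetic cohort or an
#' existing CSV table: (1) simulate or ingest the feature table; (2)
#' region-wise volumetric statistics for each requested feature, grouped by
#' treatment and by donor; (3) fixed-PC classification (confusion matrix,
#' per-class metrics) for each label target; (4) a label-permutation test per
#' target; (5) figures. All outputs are deterministic functions of the
#' configuration (JSON/CSV outputs carry no timestamps), so a rerun with the
#' same config is byte-identical.
#'
#' @param config a list (or path to a YAML file encoding one) with fields:
#'   `input` (a [synthetic_config()] or a CSV path), `labels` (character,
#'   default `c("donor_id", "treatment")`), `cv` (a [cv_config()]),
#'   `n_pcs` (default 5), `permutation_b` (default 200; set 0 to skip),
#'   `volumetric_features` (default the three volume columns),
#'   `figures` (default `TRUE`), `out_dir` (required).
#' @return the output manifest (named list of file paths), invisibly.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("run_full_pipeline: the 'yaml' package is needed to read a YAML config",
           call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop("run_full_pipeline: out_dir is required",
                                    call. = FALSE)
  labels <- config$labels %||% c("donor_id", "treatment")
  if (length(labels) == 0) stop("run_full_pipeline: at least one label target",
                                call. = FALSE)
  cv <- config$cv %||% cv_config()
  n_pcs <- config$n_pcs %||% 5
  b <- config$permutation_b %||% 200
  vol_features <- config$volumetric_features %||% c("vol_whole", "vol_mid", "vol_nuc")
  figures <- config$figures %||% TRUE

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()

  # stage 1: cohort
  table <- if (inherits(config$input, "synthetic_config")) {
    generate_cohort(config$input)
  } else if (is.character(config$input)) {
    if (!file.exists(config$input)) {
      stop("pipeline stage 'ingest': input file not found: ", config$input,
           call. = FALSE)
    }
    read_feature_table(config$input)
  } else {
    stop("pipeline stage 'ingest': input must be a synthetic_config or a CSV path",
         call. = FALSE)
  }
  manifest$cohort <- file.path(out_dir, "cohort.csv")
  write_feature_table(table, manifest$cohort)

  # stage 2: volumetric / univariate statistics
  for (feat in vol_features) {
    for (grouping in c("treatment", "donor_id")) {
      ra <- region_analysis(table, feat, grouping)
      key <- paste0("volumetrics_", feat, "_by_", grouping)
      manifest[[key]] <- file.path(out_dir, paste0(key, ".json"))
      json_write(list(
        feature = feat, grouping = grouping, transformed = ra$transformed,
        summaries = ra$summaries,
        anova = ra$anova[c("f_stat", "df_between", "df_within", "p_value",
                           "ss_between", "ss_within")],
        pairwise = as.data.frame(ra$pairwise)
      ), manifest[[key]])
    }
  }

  # stages 3-5 per label target
  for (lab in labels) {
    run <- fixed_pc_run(table, lab, n_pcs = n_pcs, config = cv)
    key <- paste0("classification_", lab)
    manifest[[key]] <- file.path(out_dir, paste0(key, ".json"))
    json_write(list(
      result = result_to_list(run$result),
      confusion = list(class_labels = run$confusion$class_labels,
                       counts = run$confusion$counts),
      report = list(per_class = run$report$per_class,
                    overall_accuracy = run$report$overall_accuracy)
    ), manifest[[key]])
    metrics_key <- paste0("metrics_", lab)
    manifest[[metrics_key]] <- file.path(out_dir, paste0(metrics_key, ".csv"))
    write_report_csv(run$report, manifest[[metrics_key]])

    if (b > 0) {
      perm <- run_permutation_test(table, lab, config = cv, b = b, n_pcs = n_pcs)
      pkey <- paste0("permutation_", lab)
      manifest[[pkey]] <- file.path(out_dir, paste0(pkey, ".json"))
      json_write(list(
        label_column = lab, observed_accuracy = perm$observed_accuracy,
        p_value = perm$p_value, b = perm$b, seed = perm$seed,
        null_accuracies = perm$null_accuracies
      ), manifest[[pkey]])
    }

    if (isTRUE(figures)) {
      fkey <- paste0("heatmap_", lab)
      manifest[[fkey]] <- file.path(out_dir, paste0(fkey, ".png"))
      render_confusion_heatmap(run$confusion, manifest[[fkey]],
                               title = paste("Classification by", lab))
    }
  }

  if (isTRUE(figures)) {
    for (feat in vol_features) {
      fkey <- paste0("boxplot_", feat)
      manifest[[fkey]] <- file.path(out_dir, paste0(fkey, ".png"))
      render_volume_boxplot(table, feat, "treatment", manifest[[fkey]])
    }
  }

  manifest$manifest <- file.path(out_dir, "manifest.json")
  # the written manifest holds file names only, so reruns into different
  # directories stay byte-identical
  json_write(lapply(manifest[setdiff(names(manifest), "manifest")], basename),
             manifest$manifest)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
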