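#' Column schema of the sperm feature table
#'
#' The pipeline's universal currency is a per-observation feature table: one
#' row per semen sample (or replicate measurement), with donor identity,
#' treatment label, donor age, and fourteen quantitative features spanning
#' CASA kinematics (TM, PM, VCL, VSL, VAP), bioenergetics (MMP), oxidative /
#' nitrosative stress markers (LPO, ROS, NO), DNA-fragmentation indices
#' (TUNEL-DFI, SCSA-DFI) and holotomography-derived region volumes
#' (whole cell, post-acrosomal/midpiece, nucleus).
#'
#' @return `treatment_levels()`: the seven legal treatment labels.
#'   `feature_columns()`: the 14 quantitative feature column names.
#'   `percent_columns()`: the feature columns measured in percent.
#'   `model_columns()`: the 15 numeric columns entering the multivariate
#'   models (age plus the 14 features).
#' @export
treatment_levels <- function() {
  c("Fresh", "CTRL-", "CTRL+", "Matcha", "Spirulina", "Horseradish", "Quercetin")
}

#' @rdname treatment_levels
#' @export
feature_columns <- function() {
  c("tm", "pm", "vcl", "vsl", "vap", "mmp", "lpo", "ros", "no",
    "tunel_dfi", "scsa_dfi", "vol_whole", "vol_mid", "vol_nuc")
}

#' @rdname treatment_levels
#' @export
percent_columns <- function() {
  c("tm", "pm", "tunel_dfi", "scsa_dfi")
}

#' @rdname treatment_levels
#' @export
model_columns <- function() {
  c("age", feature_columns())
}

metadata_columns <- function() c("donor_id", "treatment", "age")

# canonicalize treatment labels: trim whitespace, map the typographic minus
# to ASCII hyphen, and restore canonical casing by case-insensitive match
normalize_treatment <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("−", "-", x)
  lv <- treatment_levels()
  idx <- match(toupper(x), toupper(lv))
  out <- ifelse(is.na(idx), x, lv[idx])
  out
}

#' Validate a sperm feature table
#'
#' Checks the full schema and value contracts: all metadata and feature
#' columns present, no missing values in modelling columns, percentages in
#' \[0, 100\], strictly positive volumes with `vol_nuc <= vol_whole` and
#' `vol_mid <= vol_whole`, and treatment labels drawn from the closed
#' seven-label set.
#'
#' @param table a data frame to validate.
#' @param donors optional character vector of legal donor identifiers; when
#'   supplied, `donor_id` values outside it are an error.
#' @return the validated table as a [tibble::tibble()], invisibly classed
#'   `"feature_table"`, with treatment labels normalized.
#' @export
validate_feature_table <- function(table, donors = NULL) {
  required <- c(metadata_columns(), feature_columns())
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0) {
    stop("feature table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  table <- tibble::as_tibble(table)
  table$donor_id <- trimws(as.character(table$donor_id))
  table$treatment <- normalize_treatment(table$treatment)

  bad_trt <- setdiff(unique(table$treatment), treatment_levels())
  if (length(bad_trt) > 0) {
    stop("unknown treatment label(s): ", paste(bad_trt, collapse = ", "),
         "; legal labels are: ", paste(treatment_levels(), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(donors)) {
    bad_donor <- setdiff(unique(table$donor_id), donors)
    if (length(bad_donor) > 0) {
      stop("unknown donor identifier(s): ", paste(bad_donor, collapse = ", "),
           call. = FALSE)
    }
  }

  num_cols <- model_columns()
  for (col in num_cols) {
    v <- table[[col]]
    if (!is.numeric(v)) {
      stop("column '", col, "' must be numeric", call. = FALSE)
    }
    if (anyNA(v)) {
      stop("missing values in modelling column '", col, "' at row(s) ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "), call. = FALSE)
    }
    table[[col]] <- as.numeric(v)
  }
  for (col in percent_columns()) {
    v <- table[[col]]
    bad <- which(v < 0 | v > 100)
    if (length(bad) > 0) {
      stop("percentage column '", col, "' outside [0, 100] at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  for (col in c("vol_whole", "vol_mid", "vol_nuc")) {
    bad <- which(table[[col]] <= 0)
    if (length(bad) > 0) {
      stop("volume column '", col, "' must be strictly positive; violated at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  bad_nuc <- which(table$vol_nuc > table$vol_whole)
  bad_mid <- which(table$vol_mid > table$vol_whole)
  if (length(bad_nuc) > 0 || length(bad_mid) > 0) {
    stop("subcellular volume exceeds whole-cell volume at row(s) ",
         paste(utils::head(c(bad_nuc, bad_mid), 5), collapse = ", "), call. = FALSE)
  }
  class(table) <- unique(c("feature_table", class(table)))
  table
}

#' Read a sperm feature table from CSV
#'
#' Comma-separated, period decimal, UTF-8, header required. Treatment and
#' donor labels are whitespace-trimmed and case-canonicalized; the table is
#' validated on read (see [validate_feature_table()]).
#'
#' @param path path to a CSV file.
#' @param donors optional legal donor set passed to the validator.
#' @return a validated `feature_table` tibble.
#' @export
read_feature_table <- function(path, donors = NULL) {
  if (!file.exists(path)) {
    stop("feature table file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = c(donor_id = "character",
                                              treatment = "character"),
                         check.names = FALSE, stringsAsFactors = FALSE)
  validate_feature_table(raw, donors = donors)
}

#' Write a sperm feature table to CSV
#'
#' Writes in the same dialect [read_feature_table()] consumes; numeric values
#' round-trip at full double precision.
#'
#' @param table a validated feature table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  table <- validate_feature_table(table)
  out <- as.data.frame(table)
  # %.17g is the shortest representation guaranteed to round-trip a double
  for (col in model_columns()) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Arcsine square-root transform for percentage data
#'
#' The variance-stabilizing transform applied to percentage-valued features
#' (motility and DFI columns) ahead of the ANOVA stage:
#' `asin(sqrt(p / 100))`, mapping \[0, 100\] onto \[0, pi/2\] monotonically.
#'
#' @param values numeric vector of percentages in \[0, 100\].
#' @param clip_tol values within `clip_tol` outside the domain are clipped to
#'   the boundary; beyond that the call errors. Default `1e-9`.
#' @return transformed values in radians.
#' @export
arcsine_transform <- function(values, clip_tol = 1e-9) {
  if (any(values < -clip_tol | values > 100 + clip_tol, na.rm = TRUE)) {
    stop("arcsine_transform: values outside [0, 100]", call. = FALSE)
  }
  v <- pmin(pmax(values, 0), 100)
  asin(sqrt(v / 100))
}

#' Fit a per-column z-score standardizer
#'
#' Means and sample standard deviations (denominator `n - 1`) computed
#' per column, intended to be fitted on a training subset only so held-out
#' rows are standardized without information leakage. Zero-variance columns
#' are flagged degenerate and later mapped to zero by [zscore_apply()].
#'
#' @param x numeric matrix (or data frame) of observations by features.
#' @return an object of class `"standardizer"` with elements `means`, `sds`
#'   and the logical `degenerate` flag per column.
#' @export
zscore_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) {
    stop("zscore_fit: need at least 2 rows to estimate a standard deviation",
         call. = FALSE)
  }
  means <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  structure(
    list(means = means, sds = sds, degenerate = sds == 0),
    class = "standardizer"
  )
}

#' Apply a fitted standardizer
#'
#' @param std a `"standardizer"` from [zscore_fit()].
#' @param x matrix with the same column count as the fit set.
#' @return the standardized matrix; degenerate (zero-variance) columns are 0.
#' @export
zscore_apply <- function(std, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(std$means)) {
    stop("zscore_apply: column count (", ncol(x),
         ") does not match the fitted standardizer (", length(std$means), ")",
         call. = FALSE)
  }
  sds <- ifelse(std$degenerate, 1, std$sds)
  out <- sweep(sweep(x, 2, std$means, "-"), 2, sds, "/")
  if (any(std$degenerate)) out[, std$degenerate] <- 0
  out
}
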