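#' Normality and variance-homogeneity checks for grouped data
#'
#' Shapiro-Wilk per group and Levene's test (centered at the group means)
#' across groups, both flagged at `alpha`. Groups too small (n < 3) or
#' constant are marked untestable rather than failing.
#'
#' @param groups named list of numeric vectors, one per group.
#' @param alpha significance level for the flags (default 0.05).
#' @return a list with `normality_p` (per group, `NA` if untestable),
#'   `normality_ok`, `levene_p`, `homogeneity_ok`, and `untestable`.
#' @export
check_assumptions <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  norm_p <- vapply(groups, function(v) {
    if (length(v) < 3 || length(v) > 5000 || stats::sd(v) == 0) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  levene_p <- if (stats::sd(values) == 0 || any(lengths(groups) < 2)) {
    NA_real_
  } else {
    lt <- car::leveneTest(values ~ g, center = "mean")
    lt[["Pr(>F)"]][1]
  }
  list(
    normality_p = norm_p,
    normality_ok = !is.na(norm_p) & norm_p >= alpha,
    levene_p = levene_p,
    homogeneity_ok = !is.na(levene_p) && levene_p >= alpha,
    untestable = is.na(norm_p)
  )
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition, `F = MS_between / MS_within`,
#' p-value from the F distribution (fitted via `stats::lm`/`stats::anova`).
#' The degenerate all-constant input (zero total variance) is guarded and
#' reported as `F = 0`, `p = 1`. Assumption flags from [check_assumptions()]
#' ride along.
#'
#' @param groups named list of numeric vectors (>= 2 groups, none empty,
#'   total N greater than the number of groups).
#' @return an object of class `"anova_result"`: `f_stat`, `df_between`,
#'   `df_within`, `p_value`, the sums of squares, and `assumption_flags`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 2) stop("one_way_anova: need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0)) stop("one_way_anova: empty group", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  n <- length(values)
  k <- nlevels(g)
  if (n <= k) stop("one_way_anova: total N must exceed the number of groups",
                   call. = FALSE)
  ss_total <- sum((values - mean(values))^2)
  if (ss_total == 0) {
    res <- list(f_stat = 0, df_between = k - 1L, df_within = n - k,
                p_value = 1, ss_between = 0, ss_within = 0, ss_total = 0,
                ms_between = 0, ms_within = 0,
                assumption_flags = check_assumptions(groups))
    return(structure(res, class = "anova_result"))
  }
  a <- stats::anova(stats::lm(values ~ g))
  structure(
    list(f_stat = a$`F value`[1],
         df_between = a$Df[1], df_within = a$Df[2],
         p_value = a$`Pr(>F)`[1],
         ss_between = a$`Sum Sq`[1], ss_within = a$`Sum Sq`[2],
         ss_total = ss_total,
         ms_between = a$`Mean Sq`[1], ms_within = a$`Mean Sq`[2],
         assumption_flags = check_assumptions(groups)),
    class = "anova_result"
  )
}

#' Bonferroni-adjusted pairwise comparisons
#'
#' All-pairs two-sample t tests. By default each pair uses the pooled
#' within-group variance from the one-way ANOVA (the classical Bonferroni
#' post hoc after ANOVA) with `N - k` degrees of freedom; `welch = TRUE`
#' switches to per-pair Welch tests. Adjusted p-values are
#' `min(1, raw_p * m)` with `m = k (k - 1) / 2`, and each pair receives a
#' significance tier (`ns`, `p<=0.05`, `p<=0.01`) following the two-level
#' letter convention of box-plot annotations.
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @param welch use Welch per-pair tests instead of the pooled variance.
#' @return an object of class `"pairwise_table"`: a tibble with `group1`,
#'   `group2`, `estimate` (mean difference), `t`, `raw_p`, `adjusted_p`,
#'   `tier`; the number of pairs `m` is an attribute.
#' @export
bonferroni_pairwise <- function(groups, welch = FALSE) {
  stopifnot(is.list(groups))
  if (length(groups) < 2) stop("bonferroni_pairwise: need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0)) stop("bonferroni_pairwise: empty group", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  k <- length(groups)
  nm <- names(groups)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)

  ns <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  if (!welch) {
    ss_w <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
    df_w <- sum(ns) - k
    if (df_w < 1) stop("bonferroni_pairwise: no within-group degrees of freedom",
                       call. = FALSE)
    s2 <- ss_w / df_w
  }
  est <- t_stat <- raw_p <- numeric(m)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    est[j] <- means[i1] - means[i2]
    if (welch) {
      tt <- stats::t.test(groups[[i1]], groups[[i2]])
      t_stat[j] <- unname(tt$statistic)
      raw_p[j] <- tt$p.value
    } else {
      se <- sqrt(s2 * (1 / ns[i1] + 1 / ns[i2]))
      if (se == 0) {
        t_stat[j] <- if (est[j] == 0) 0 else sign(est[j]) * Inf
        raw_p[j] <- if (est[j] == 0) 1 else 0
      } else {
        t_stat[j] <- est[j] / se
        raw_p[j] <- 2 * stats::pt(-abs(t_stat[j]), df_w)
      }
    }
  }
  adj <- pmin(1, raw_p * m)
  tier <- ifelse(adj <= 0.01, "p<=0.01", ifelse(adj <= 0.05, "p<=0.05", "ns"))
  out <- tibble::tibble(
    group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
    estimate = est, t = t_stat, raw_p = raw_p, adjusted_p = adj, tier = tier
  )
  attr(out, "m") <- m
  class(out) <- c("pairwise_table", class(out))
  out
}

#' Region-wise (or feature-wise) group analysis of a feature table
#'
#' The univariate analysis pathway for one feature grouped by treatment or
#' by donor: per-group summaries, assumption-checked one-way ANOVA, and
#' Bonferroni pairwise contrasts. Percentage features are arcsine-transformed
#' before testing (summaries stay on the original measurement scale).
#'
#' @param table a validated feature table.
#' @param feature one of [feature_columns()].
#' @param grouping `"treatment"` or `"donor_id"`.
#' @param welch passed to [bonferroni_pairwise()].
#' @return a list with `summaries` (tibble: group, n, mean, sd), `anova`
#'   (an `"anova_result"`), `pairwise` (a `"pairwise_table"`), `feature`,
#'   `grouping`, and `transformed` (whether the arcsine transform applied).
#' @export
region_analysis <- function(table, feature, grouping = c("treatment", "donor_id"),
                            welch = FALSE) {
  table <- validate_feature_table(table)
  grouping <- match.arg(grouping)
  if (!feature %in% feature_columns()) {
    stop("region_analysis: unknown feature '", feature, "'", call. = FALSE)
  }
  g_raw <- table[[grouping]]
  lv <- if (grouping == "treatment") {
    intersect(treatment_levels(), unique(g_raw))
  } else {
    unique(g_raw)
  }
  values <- table[[feature]]
  transformed <- feature %in% percent_columns()
  tvalues <- if (transformed) arcsine_transform(values) else values

  groups_raw <- split(values, factor(g_raw, levels = lv))
  groups_t <- split(tvalues, factor(g_raw, levels = lv))

  summaries <- tibble::tibble(
    group = lv,
    n = as.integer(lengths(groups_raw)),
    mean = vapply(groups_raw, mean, numeric(1)),
    sd = vapply(groups_raw, stats::sd, numeric(1))
  )
  list(
    summaries = summaries,
    anova = one_way_anova(groups_t),
    pairwise = bonferroni_pairwise(groups_t, welch = welch),
    feature = feature,
    grouping = grouping,
    transformed = transformed
  )
}
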