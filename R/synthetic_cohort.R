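#' Hierarchical effect profile for the synthetic cohort generator
#'
#' Encodes the additive effect structure the generator imposes on each
#' feature: a grand baseline, a per-donor Gaussian random offset, a
#' freeze-thaw shift shared by all six frozen treatments, small
#' treatment-specific (antioxidant) offsets, and residual Gaussian noise.
#' All vectors are named by [feature_columns()].
#'
#' @param baseline_means named numeric vector, one grand mean per feature, in
#'   the feature's units; percentage baselines must lie strictly inside
#'   (0, 100).
#' @param donor_sd named non-negative vector: SD of the per-donor offsets.
#' @param freeze_shift named vector: additive shift applied to every
#'   non-Fresh row.
#' @param antiox_shift numeric matrix of small treatment-specific offsets,
#'   rows named by the frozen treatment labels, columns by feature.
#' @param noise_sd named non-negative vector: residual SD.
#' @return an object of class `"effect_profile"`.
#' @export
effect_profile <- function(baseline_means, donor_sd, freeze_shift,
                           antiox_shift = NULL, noise_sd) {
  feats <- feature_columns()
  check_named <- function(v, what) {
    if (!all(feats %in% names(v))) {
      stop("effect_profile: '", what, "' must be named by all 14 feature columns",
           call. = FALSE)
    }
    v[feats]
  }
  baseline_means <- check_named(baseline_means, "baseline_means")
  donor_sd <- check_named(donor_sd, "donor_sd")
  freeze_shift <- check_named(freeze_shift, "freeze_shift")
  noise_sd <- check_named(noise_sd, "noise_sd")
  if (any(donor_sd < 0) || any(noise_sd < 0)) {
    stop("effect_profile: SDs must be non-negative", call. = FALSE)
  }
  pc <- percent_columns()
  if (any(baseline_means[pc] <= 0 | baseline_means[pc] >= 100)) {
    stop("effect_profile: percentage baselines must lie inside (0, 100)",
         call. = FALSE)
  }
  frozen <- setdiff(treatment_levels(), "Fresh")
  if (is.null(antiox_shift)) {
    antiox_shift <- matrix(0, nrow = length(frozen), ncol = length(feats),
                           dimnames = list(frozen, feats))
  } else {
    if (!all(frozen %in% rownames(antiox_shift)) ||
        !all(feats %in% colnames(antiox_shift))) {
      stop("effect_profile: antiox_shift must have the six frozen treatments ",
           "as rows and the 14 features as columns", call. = FALSE)
    }
    antiox_shift <- antiox_shift[frozen, feats, drop = FALSE]
  }
  structure(
    list(baseline_means = baseline_means, donor_sd = donor_sd,
         freeze_shift = freeze_shift, antiox_shift = antiox_shift,
         noise_sd = noise_sd),
    class = "effect_profile"
  )
}

#' Default effect profile emulating a donor-dominated cryopreservation study
#'
#' The default profile reproduces the qualitative variance structure of a
#' stallion cryopreservation experiment: donor random effects dominate the
#' motility, bioenergetic and lipid-peroxidation/nitric-oxide assays
#' (donor SD = 1.5 x residual SD on those 8 features; 0.6 x on ROS, the two
#' DFI indices and the three volumes); freezing shifts motility/velocity/MMP
#' and whole-cell/midpiece volumes down by 1.5 x residual SD and the
#' oxidative-stress and DNA-fragmentation markers up by 3 x residual SD
#' (post-thaw DFI and ROS roughly double in equine semen, a much larger
#' fold-change than the kinematic losses); nuclear volume carries no freeze
#' effect at all; and antioxidant-specific offsets are small (at most
#' 0.2 x residual SD), with matcha, horseradish and the commercial extender
#' (CTRL+) reducing midpiece volume twice as much as spirulina and quercetin.
#' Baselines are plausible literature-scale values for equine semen; no
#' fidelity to any particular measured cohort is claimed.
#'
#' @return an `"effect_profile"`.
#' @export
default_effect_profile <- function() {
  feats <- feature_columns()
  baseline <- c(
    tm = 78, pm = 60, vcl = 120, vsl = 60, vap = 85,
    mmp = 2.0, lpo = 100, ros = 150, no = 120,
    tunel_dfi = 10, scsa_dfi = 12,
    vol_whole = 28, vol_mid = 9, vol_nuc = 5
  )
  noise <- c(
    tm = 5, pm = 5, vcl = 8, vsl = 6, vap = 6,
    mmp = 0.25, lpo = 12, ros = 18, no = 15,
    tunel_dfi = 2, scsa_dfi = 2.5,
    vol_whole = 1.5, vol_mid = 0.6, vol_nuc = 0.4
  )
  donor_heavy <- c("tm", "pm", "vcl", "vsl", "vap", "mmp", "lpo", "no")
  donor <- ifelse(feats %in% donor_heavy, 1.5, 0.6) * noise[feats]
  names(donor) <- feats

  down <- c("tm", "pm", "vcl", "vsl", "vap", "mmp", "vol_whole", "vol_mid")
  up <- c("lpo", "ros", "no", "tunel_dfi", "scsa_dfi")
  freeze <- stats::setNames(numeric(length(feats)), feats)
  freeze[down] <- -1.5 * noise[down]
  freeze[up] <- 3 * noise[up]
  freeze["vol_nuc"] <- 0

  frozen <- setdiff(treatment_levels(), "Fresh")
  antiox <- matrix(0, nrow = length(frozen), ncol = length(feats),
                   dimnames = list(frozen, feats))
  antiox[c("Matcha", "Horseradish", "CTRL+"), "vol_mid"] <- -0.2 * noise["vol_mid"]
  antiox[c("Spirulina", "Quercetin"), "vol_mid"] <- -0.1 * noise["vol_mid"]

  effect_profile(baseline, donor, freeze, antiox, noise)
}

#' Configuration of a synthetic cohort draw
#'
#' Mirrors the study design: `n_donors` stallions (default 10, labelled
#' "#3" to "#12"), each contributing one fresh aliquot plus six frozen
#' aliquots (the seven treatment labels), measured `replicates` times.
#' Donor ages in years are sampled uniformly from 4-17 (without replacement
#' while possible) and held constant across a donor's rows, so age partially
#' identifies donors, as in real data.
#'
#' @param n_donors number of donors (>= 2).
#' @param treatments treatment labels; must include "Fresh" whenever the
#'   profile's freeze shift is nonzero.
#' @param replicates rows per donor-by-treatment cell (>= 1).
#' @param profile an [effect_profile()]; default [default_effect_profile()].
#' @param seed integer RNG seed; the cohort is fully reproducible from it.
#' @param age_per_donor if `TRUE` (default) ages are drawn once per donor;
#'   if `FALSE` they are drawn independently per row, severing the age-donor
#'   link (used by [null_cohort()] so no column carries label information).
#' @return an object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_donors = 10, treatments = treatment_levels(),
                             replicates = 3, profile = default_effect_profile(),
                             seed = 1L, age_per_donor = TRUE) {
  if (n_donors < 2) stop("synthetic_config: n_donors must be >= 2", call. = FALSE)
  if (replicates < 1) stop("synthetic_config: replicates must be >= 1", call. = FALSE)
  bad <- setdiff(treatments, treatment_levels())
  if (length(bad) > 0) {
    stop("synthetic_config: unknown treatment(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!inherits(profile, "effect_profile")) {
    stop("synthetic_config: profile must be an effect_profile", call. = FALSE)
  }
  if (any(profile$freeze_shift != 0) && !("Fresh" %in% treatments)) {
    stop("synthetic_config: treatments must include 'Fresh' when freeze ",
         "effects are nonzero", call. = FALSE)
  }
  structure(
    list(n_donors = n_donors, treatments = treatments, replicates = replicates,
         profile = profile, seed = as.integer(seed),
         age_per_donor = isTRUE(age_per_donor)),
    class = "synthetic_config"
  )
}

#' Generate a synthetic cohort feature table
#'
#' Each feature value is
#' `baseline + donor_offset(donor) + [treatment != Fresh] * freeze_shift +
#' antiox_shift(treatment) + noise`, with percentages clipped to \[0, 100\]
#' and volumes floored at a small positive bound. One RNG stream is consumed
#' in a fixed order -- donor offsets, then ages, then residual noise -- so
#' increasing `replicates` leaves the donor offsets (and ages) unchanged.
#'
#' @param config a [synthetic_config()].
#' @return a validated `feature_table` with
#'   `n_donors * length(treatments) * replicates` rows, ordered donor by
#'   treatment by replicate.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("generate_cohort: config must be a synthetic_config", call. = FALSE)
  }
  pr <- config$profile
  feats <- feature_columns()
  nf <- length(feats)
  nd <- config$n_donors
  donors <- paste0("#", seq(3, length.out = nd))
  nrow_total <- nd * length(config$treatments) * config$replicates

  withr::with_seed(config$seed, {
    donor_offsets <- matrix(stats::rnorm(nd * nf), nrow = nd, ncol = nf,
                            dimnames = list(donors, feats))
    donor_offsets <- sweep(donor_offsets, 2, pr$donor_sd, "*")
    if (config$age_per_donor) {
      ages <- if (nd <= 14) sample(4:17, nd) else sample(4:17, nd, replace = TRUE)
      names(ages) <- donors
    } else {
      row_ages <- sample(4:17, nrow_total, replace = TRUE)
    }
    noise <- matrix(stats::rnorm(nrow_total * nf), nrow = nrow_total, ncol = nf)
    noise <- sweep(noise, 2, pr$noise_sd, "*")
  })

  grid <- expand.grid(replicate = seq_len(config$replicates),
                      treatment = config$treatments,
                      donor_id = donors,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("donor_id", "treatment", "replicate")]

  x <- matrix(rep(pr$baseline_means, each = nrow_total), nrow = nrow_total,
              dimnames = list(NULL, feats))
  x <- x + donor_offsets[grid$donor_id, , drop = FALSE]
  frozen <- grid$treatment != "Fresh"
  x[frozen, ] <- x[frozen, ] + rep(pr$freeze_shift, each = sum(frozen))
  if (any(frozen)) {
    x[frozen, ] <- x[frozen, ] + pr$antiox_shift[grid$treatment[frozen], , drop = FALSE]
  }
  x <- x + noise

  pc <- percent_columns()
  x[, pc] <- pmin(pmax(x[, pc], 0), 100)
  vols <- c("vol_whole", "vol_mid", "vol_nuc")
  x[, vols] <- pmax(x[, vols], 0.01)
  x[, "vol_mid"] <- pmin(x[, "vol_mid"], x[, "vol_whole"])
  x[, "vol_nuc"] <- pmin(x[, "vol_nuc"], x[, "vol_whole"])

  tab <- tibble::tibble(
    donor_id = grid$donor_id,
    treatment = grid$treatment,
    age = if (config$age_per_donor) as.numeric(ages[grid$donor_id]) else as.numeric(row_ages)
  )
  tab <- cbind(tab, tibble::as_tibble(x))
  validate_feature_table(tab, donors = donors)
}

#' Generate a null cohort with uninformative labels
#'
#' As [generate_cohort()] but with all structured effects removed
#' (`donor_sd = 0`, `freeze_shift = 0`, `antiox_shift = 0`) and ages drawn
#' independently per row, so neither the donor nor the treatment labels carry
#' any information: every modelling column is pure noise around its baseline.
#' Used to calibrate permutation tests and to audit the cross-validation
#' machinery for information leakage.
#'
#' @param config a [synthetic_config()].
#' @return a validated `feature_table`.
#' @export
null_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("null_cohort: config must be a synthetic_config", call. = FALSE)
  }
  pr <- config$profile
  zero <- stats::setNames(numeric(length(feature_columns())), feature_columns())
  null_profile <- effect_profile(
    baseline_means = pr$baseline_means,
    donor_sd = zero,
    freeze_shift = zero,
    antiox_shift = NULL,
    noise_sd = pr$noise_sd
  )
  null_config <- synthetic_config(
    n_donors = config$n_donors, treatments = config$treatments,
    replicates = config$replicates, profile = null_profile,
    seed = config$seed, age_per_donor = FALSE
  )
  generate_cohort(null_config)
}
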