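#!/usr/bin/env Rscript
# Step 3: multivariate classification.
#
# Z-score -> PCA -> LDA inside stratified nested 5-fold cross-validation.
# The nested run searches PC counts 2-15 in the inner loop (median selection
# reported); the fixed-5-PC run produces the confusion matrices and
# per-class metrics.

library(equicryo)

seed <- 42
cohort <- read_feature_table("results/cohort.csv")
cfg <- cv_config(seed = seed)

for (lab in c("donor_id", "treatment")) {
  nested <- nested_cv_run(cohort, lab, cfg)
  fixed <- fixed_pc_run(cohort, lab, n_pcs = 5, config = cfg)
  cat(sprintf("%-9s: nested accuracy %.3f (median PCs %g), fixed-5-PC accuracy %.3f\n",
              lab, nested$mean_accuracy, nested$median_pcs,
              fixed$result$mean_accuracy))
  write_report_csv(fixed$report, sprintf("results/metrics_%s.csv", lab))
  render_confusion_heatmap(fixed$confusion,
                           sprintf("results/heatmap_%s.png", lab),
                           title = paste("Classification by", lab))
}
cat("expected pattern: donor identity classifies far above its 0.10 chance\n")
cat("level; treatment stays near chance except for a cleanly separated Fresh class.\n")
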