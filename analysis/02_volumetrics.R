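#!/usr/bin/env Rscript
# Step 2: region-wise volumetric statistics.
#
# One-way ANOVA plus Bonferroni post hoc contrasts for each refractive-
# index-derived region volume, grouped by treatment (antioxidant pathway)
# and by donor (inter-stallion variability pathway).

library(equicryo)

cohort <- read_feature_table("results/cohort.csv")

for (feat in c("vol_whole", "vol_mid", "vol_nuc")) {
  ra <- region_analysis(cohort, feat, "treatment")
  fresh <- ra$pairwise[ra$pairwise$group1 == "Fresh" | ra$pairwise$group2 == "Fresh", ]
  cat(sprintf("%-9s by treatment: ANOVA F(%d,%d) = %.2f, p = %.3g; %d/6 Fresh contrasts significant\n",
              feat, ra$anova$df_between, ra$anova$df_within, ra$anova$f_stat,
              ra$anova$p_value, sum(fresh$adjusted_p <= 0.05)))
  utils::write.csv(as.data.frame(ra$pairwise),
                   sprintf("results/pairwise_%s_by_treatment.csv", feat),
                   row.names = FALSE)

  rd <- region_analysis(cohort, feat, "donor_id")
  cat(sprintf("%-9s by donor:     ANOVA F(%d,%d) = %.2f, p = %.3g (inter-stallion variability)\n",
              feat, rd$anova$df_between, rd$anova$df_within, rd$anova$f_stat,
              rd$anova$p_value))
  utils::write.csv(as.data.frame(rd$summaries),
                   sprintf("results/summary_%s_by_donor.csv", feat),
                   row.names = FALSE)
}
cat("expected pattern: whole-cell and midpiece volumes drop after freezing;\n")
cat("nuclear volume does not; donors differ strongly in all regions.\n")
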