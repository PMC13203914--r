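# equicryo

Donor-structured analysis of equine sperm cryopreservation experiments.

Semen from a panel of stallions is frozen under several conditions (a base
extender, a commercial extender, and antioxidant-supplemented variants) and
profiled with CASA kinematics (TM, PM, VCL, VSL, VAP), bioenergetic and
redox markers (MMP, LPO, ROS, NO), DNA-fragmentation indices (TUNEL-DFI,
SCSA-DFI) and holotomography-derived region volumes (whole cell,
post-acrosomal/midpiece, nucleus). Two questions follow:

* **Does donor identity or freezing treatment structure the data?**
  Answered by classification: features are z-scored, reduced by PCA, and
  classified with multiclass LDA,
  $\delta_c(x) = x^\top\Sigma^{-1}\mu_c - \tfrac12\mu_c^\top\Sigma^{-1}\mu_c + \log\pi_c$,
  inside stratified **nested 5-fold cross-validation** (inner loop selects
  the PC count from 2–15; a fixed-5-PC mode produces confusion matrices and
  per-class sensitivity/specificity/precision/F1). Significance comes from a
  **label-permutation test**: the whole pipeline is rerun on shuffled labels
  and $p = \#\{\text{null} \ge \text{observed}\}/B$.
* **Which regions shrink after freezing, and do antioxidants help?**
  Answered per region by one-way ANOVA (Shapiro-Wilk/Levene assumption
  flags, arcsine transform for percentage features) with Bonferroni post hoc
  contrasts.

Because per-sample tables from such studies are rarely deposited, the
package includes a first-class synthetic-cohort generator
(`generate_cohort()`, `null_cohort()`) whose defaults emulate the
hierarchical structure of a real study — dominant donor random effects, a
strong freeze–thaw shift that spares nuclear volume, and weak
antioxidant-specific offsets — so every stage is testable end to end. See
`vignettes/methods.Rmd` for the model, parameter choices, and limitations.

## Worked example

```r
library(equicryo)

cohort <- generate_cohort(synthetic_config(seed = 42))   # 210 rows
cfg <- cv_config(seed = 42)

fixed_pc_run(cohort, "donor_id", n_pcs = 5, config = cfg)$result$mean_accuracy
#> [1] 0.8333333
fixed_pc_run(cohort, "treatment", n_pcs = 5, config = cfg)$result$mean_accuracy
#> [1] 0.2380952
region_analysis(cohort, "vol_nuc", "treatment")$anova$p_value
#> [1] 0.4162901
```

Donor identity classifies at 0.83 against a 0.10 chance level while
treatment stays near its 0.14 chance level (only the Fresh class separates
cleanly), and nuclear volume shows no treatment effect — the
donor-dominance pattern the pipeline is designed to detect.

The same workflow, narrated step by step, lives in `analysis/`:

```sh
Rscript analysis/01_simulate.R      # draw the cohort and a null cohort
Rscript analysis/02_volumetrics.R   # region-wise ANOVA + Bonferroni contrasts
Rscript analysis/03_classify.R      # nested CV and fixed-5-PC classification
Rscript analysis/04_permutation.R   # permutation p-values + calibration check
Rscript analysis/05_report.R        # one-shot report bundle with figures
```

Step 2, for example, prints:

```
vol_mid   by treatment: ANOVA F(6,203) = 9.74, p = 2e-09; 6/6 Fresh contrasts significant
vol_nuc   by treatment: ANOVA F(6,203) = 1.02, p = 0.416; 0/6 Fresh contrasts significant
vol_nuc   by donor:     ANOVA F(9,200) = 8.42, p = 1.25e-10 (inter-stallion variability)
```

i.e. freezing reduces midpiece volume under every condition, nuclear volume
is untouched by treatment, yet donors differ strongly everywhere.

The input CSV format (one row per observation; columns `donor_id`,
`treatment`, `age`, and the 14 features) is documented in
`inst/extdata/feature_table.schema.json`; `read_feature_table()` validates
ranges, volume ordering and the closed treatment-label set on read.

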