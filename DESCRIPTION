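Package: equicryo
Title: Multivariate Classification and Volumetric Statistics for Equine
    Sperm Cryopreservation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for donor-structured stallion semen
    cryopreservation experiments combining computer-assisted sperm analysis
    (CASA) kinematics, redox and DNA-integrity markers, and
    holotomography-derived region volumes. Provides a validated feature-table
    format, a hierarchical synthetic-cohort generator with donor random
    effects and freeze/antioxidant shifts, in-package PCA and linear
    discriminant analysis embedded in nested stratified cross-validation with
    inner-loop selection of the principal-component count, label-permutation
    significance testing of classifier accuracy, per-class classification
    metrics, and one-way ANOVA with Bonferroni post hoc contrasts for
    region-wise volumetrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    withr,
    jsonlite,
    ggplot2,
    car
Suggests:
    testthat (>= 3.0.0),
    MASS,
    class,
    optparse,
    yaml
Config/testthat/edition: 3
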