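Package: nbsga
Title: Gestational Age Estimation from Newborn Screening Metabolic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and modelling pipeline for postnatal gestational age (GA)
    estimation from dried-blood-spot newborn screening analytes. Generates
    multi-site synthetic screening cohorts with GA-dependent analyte profiles
    (including a declining fetal-to-adult hemoglobin ratio), applies the standard
    metabolomic preparation steps (Tukey-fence winsorization, natural log
    transform, pareto scaling), screens analytes by partial Spearman correlation,
    fits baseline and elastic-net regression models with restricted cubic splines
    and pairwise interactions, and validates them internally and externally with
    MAE/RMSE, agreement bands, bootstrap percentile confidence intervals,
    preterm and small-for-gestational-age subgroup reports, and
    calibration-in-the-large of the preterm birth rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
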