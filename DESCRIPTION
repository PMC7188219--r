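Package: mrcost
Title: Mendelian Randomization for the Causal Effect of Adiposity on Hospital Costs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Instrumental-variable estimation of the causal effect of a continuous
    exposure (body mass index) on per-person-year inpatient hospital costs using
    germline genetic variants. Provides a synthetic biobank-cohort generator with a
    two-part (zero-inflated gamma) cost model, GWAS summary-statistic harmonization,
    LD clumping, allele scores and instrument diagnostics, the summary-data estimator
    suite (Wald ratio, inverse-variance weighted, MR-Egger, penalized weighted median,
    weighted mode, robust adjusted profile score, multivariable MR), non-linear MR by
    residual stratification with fractional-polynomial, quadratic and trend tests,
    within-family fixed-effect IV with family-clustered errors, gene-by-environment
    interaction MR, conventional OLS and gamma-GLM comparators, and policy cost
    projections. Tibble-first interfaces with broom-style tidiers and ggplot2 plots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    sandwich,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
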