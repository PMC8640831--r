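Package: gestaliver
Title: Maternal Liver Volumetry, Abdominal MRI Segmentation, and Clamp
    Physiology Across a Pregnancy Cycle
Version: 0.1.0
Authors@R:
    person("Repository", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for studying reproductive-state control of maternal
    liver size from abdominal MRI: synthetic 3D abdominal phantoms with
    known tissue labels, a five-class segmentation pipeline (N4-style
    bias-field correction, adipose thresholding, compact-watershed muscle
    segmentation, morphological extraction of the subcutaneous fat shell,
    visceral fat by subtraction, uterus/liver exclusion masks),
    slice-summation liver volumetry with a measurement-error-aware
    gain/no-change/loss classifier, hyperinsulinemic-euglycemic clamp
    metrics (Steele steady-state endogenous glucose production, insulin
    suppression, glucose disposal), densitometric body composition with
    pregnancy-adjusted fat-free-mass density, weighted linear calibration
    curves for LC-MS/MS quantification, a seeded synthetic-cohort
    generator with the cohort's printed statistical structure, and the
    paired-test / correlation-battery / subgroup statistics stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
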