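Package: dietshift
Title: Dietary Replacement Scenarios, Habitual Nutrient Intake and
    Environmental Footprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates replacement of meat and dairy products with
    plant-based alternatives in two-recall (24-hour) food consumption
    surveys, under equal-weight and equal-energy substitution strategies
    with seeded uniform allocation over mapped alternative foods.
    Estimates habitual (usual) nutrient-intake distributions from
    repeated recalls with a one-part Box-Cox measurement-error model
    (between/within variance separation, shrinkage and Gauss-Hermite
    back-transformation), derives the population proportion below the
    Estimated Average Requirement with stratified person-level bootstrap
    confidence intervals, and computes survey-weighted greenhouse-gas,
    land-use and water footprints of each diet with relative differences
    versus the reference. Includes a synthetic survey generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
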