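Package: vitdmr
Title: Linear and Nonlinear Mendelian Randomization for Vitamin D and Grip Strength
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the dose-response relationship between circulating
    25-hydroxyvitamin D (25(OH)D) and maximum grip strength, combining an
    observational arm (fractional-polynomial regression with likelihood-ratio
    nonlinearity tests and age-stratified interaction tests) with Mendelian
    randomization using a weighted allele score: linear MR via the Wald ratio,
    and nonlinear MR via doubly-ranked stratification, stratum-level localized
    average causal effects (LACE), fractional-polynomial meta-regression and
    integration to a reference-anchored causal curve. Includes a calibrated
    synthetic cohort generator emulating a large population biobank so the
    whole pipeline is testable without access to restricted data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
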