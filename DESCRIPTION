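Package: olfpt
Title: Statistical Evaluation of Olfactometric Proficiency Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation chain for inter-laboratory proficiency tests in
    dynamic olfactometry: robust consensus odor thresholds from pooled
    log-scale participant results (ISO 13528 Algorithm A) with back-transformed
    uncertainty intervals, assigned values and adaptive z-score proficiency
    assessment with pass/fail verdicts, recovery statistics, and ISO 5725-2
    repeatability/reproducibility variance components with expanded (k = 2)
    measurement uncertainties on the odor-level (decibel) scale. Includes a
    seeded generator of synthetic inter-laboratory studies with laboratory
    bias, replicate noise and dosing drift for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
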