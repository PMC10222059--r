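Package: popvuln
Title: Population-Level Climate-Change Vulnerability Analysis for Narrow-Range Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workbench for assessing how the demographic structure of
    censused plant populations relates to their projected vulnerability to climate
    change. Provides collinearity-filtered predictor selection (Pearson r and VIF),
    a TSS-weighted ensemble of habitat-suitability learners fitted on presences and
    random pseudo-absences, a standardized per-cell Climate Change Vulnerability
    Index (CCVI) over the present-distribution footprint, stem-length-based census
    summaries (life stages, occupancy area, densities, skewness), and the linear,
    binomial and robust-linear association models linking demography to
    vulnerability. A seeded synthetic-landscape generator makes the whole pipeline
    testable without geospatial downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    glmnet,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
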