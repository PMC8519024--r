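Package: gtridge
Title: Globaltest Confidence Regions and Ridge Tuning-Parameter Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Confidence regions for regression coefficients in low and high
    dimensions, built by inverting the globaltest score statistic, and their
    use for selecting the ridge-regression tuning parameter: the selected
    model is the least complex point on the ridge path that still lies
    inside a 1-alpha confidence region.  Supports linear, logistic and Cox
    models, exact quadratic-form p-values by Imhof's characteristic-function
    inversion, the Scheffe (F-test) region as a low-dimensional baseline,
    information-criterion and cross-validation selectors on the ridge
    effective degrees of freedom, cross-validated partial likelihood and
    censoring-weighted Brier scores for survival prediction, and seeded
    synthetic-data generators for simulation studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
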