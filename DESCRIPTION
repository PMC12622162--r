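Package: vepkit
Title: Functional-Evidence Variant Effect Prediction, ACMG Calibration and
    Genetic Epidemiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds balanced functional and clinical training sets for missense
    variant effect prediction, eliminates variant-level training circularity by
    recursive score omission over a tool registry, trains gradient-boosted
    classifiers in three feature regimes (clinical-trained tools included,
    excluded, or no predictor scores at all), calibrates continuous scores to
    ACMG/AMP PP3/BP4 evidence strengths via local likelihood ratios, and derives
    downstream genetic-epidemiology quantities (cumulative allele frequency,
    carrier frequency, genetic prevalence under Hardy-Weinberg assumptions, and
    Bayesian penetrance). A synthetic-data module generates every input with
    known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
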