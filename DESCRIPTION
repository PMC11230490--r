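Package: ordival
Title: Risk and Ambiguity Attitudes for Ordinal and Monetary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for estimating individual attitudes toward risk and
    ambiguity from binary lottery-versus-reference choices when outcomes are
    quantitative (monetary gains) or qualitative but ordered (levels of
    improvement in a medical condition). Implements the two-domain task
    design, a synthetic two-phase cohort simulator with known generative
    parameters, the exclusion filters used for online cohorts, model-free
    choice-proportion summaries with 50%-risk-corrected ambiguity attitudes,
    maximum-likelihood fitting of ordinal- and rating-based subjective-value
    models with a softmax choice rule (multistart Nelder-Mead), model
    comparison by BIC and 5-fold cross-validation, and cross-domain /
    test-retest consistency analyses based on Spearman correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
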