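Package: pdqmap
Title: Mapping PDQ-39 Scores to EQ-5D-3L Utilities in Two-Arm Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores the 39-item Parkinson's Disease Questionnaire (PDQ-39)
    into its eight 0-100 subscale indices, predicts EQ-5D-3L dimension
    response levels from the subscale profile with two families of
    response-mapping models (an ordinal regression with Cauchit link, and a
    multinomial logit with age and gender covariates), converts predicted
    health states to utilities with country value sets (tariffs), and runs
    the longitudinal two-arm trial comparison: change from baseline within
    and between arms with Bonferroni-adjusted Student's t-tests,
    repeated-measures ANOVA, responsiveness statistics (effect size,
    standardized response mean), and Hoehn & Yahr severity-stratified
    distribution summaries. Includes a synthetic two-arm longitudinal trial
    generator with known ground truth so the whole pipeline is testable
    without access to restricted trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
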