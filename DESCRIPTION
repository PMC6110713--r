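Package: proxyrisk
Title: Model-Based Analysis of Risky Decisions for Self and for Others
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and simulation tools for studying risky decision
    making for oneself versus for an anonymous other. Implements the
    quasi-maximin utility model (a weighted mix of an option's minimum
    outcome and its expected value) with softmax choice likelihood and
    per-subject maximum-likelihood estimation; Mouselab-style
    process-tracing analysis (quartile view shares, first-view bias
    GLMM, dwell-difference mixed models); velocity/acceleration-threshold
    classification of gaze samples into fixations and saccades with
    area-of-interest dwell statistics; model-based fMRI design-matrix
    construction (canonical HRF, RT-duration boxcars, mean-centered
    parametric modulators, discrete-cosine high-pass basis) with OLS GLM
    fitting and generalized psychophysiological-interaction (gPPI)
    regressors; robust percentage-bend correlation and within-subject
    ANOVA; and a synthetic-data generator that emulates the full study so
    every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
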