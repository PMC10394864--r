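Package: tlroadmap
Title: Targeted Learning Roadmap for Point-Treatment Effects in
    Observational Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the Targeted Learning roadmap for a binary
    point-treatment causal question on an observational cohort: cohort
    validation, synthetic cohort generation with known counterfactual
    truth, cross-validated super-learner ensembles for the outcome
    regression and propensity score, targeted minimum loss-based
    estimation (TMLE) of the marginal risk difference (and risk ratio /
    odds ratio) with influence-curve inference, positivity and
    propensity-overlap diagnostics, and a non-parametric causal-gap
    sensitivity analysis including the G-value.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    mgcv,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
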