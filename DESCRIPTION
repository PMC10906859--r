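Package: dualfactor
Title: Dual-Factor Mental Health Classification for Adolescent Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores the Mental Health Continuum Short Form (MHC-SF),
    Strengths and Difficulties Questionnaire (SDQ) and Child and Youth
    Resilience Measure (CYRM-12) from item-level survey responses, crosses
    the MHC-SF categorical diagnosis with SDQ caseness into the four
    dual-factor mental-health status groups (complete, symptomatic-but-
    content, vulnerable, troubled), and compares the groups with chi-squared
    and Fisher tests, one-way ANOVA with Tukey post-hoc comparisons, Cohen's
    h and d effect sizes, and binary logistic regression with Nagelkerke
    R-squared, Hosmer-Lemeshow calibration and VIF collinearity screens.
    Includes a Gaussian-copula synthetic cohort generator so the complete
    pipeline can be exercised and validated without access to raw survey
    data, plus exclusion-cascade auditing and table-shaped reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    car,
    optparse
Config/testthat/edition: 3
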