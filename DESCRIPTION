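Package: costtriage
Title: Cost-Sensitive Three-Tier Postoperative Triage Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models postoperative allocation of neurosurgical patients to
    regular ward, intermediate care (IMC) or intensive care (ICU) as a
    cost-sensitive three-class problem. Provides a zeta-parameterized cost
    matrix blending staffing-resource costs (from nurse-to-patient ratios)
    with under-triage harm costs (from inverse class frequencies), a custom
    expected-cost softmax objective with analytic gradient and Hessian for
    gradient-boosted trees, a zeta sweep with inflection-point operating-point
    selection, multiclass discrimination metrics (AUCmu, weighted F1), dual
    gain/SHAP feature importance, a seeded synthetic cohort generator, and a
    cohort-comparison statistics battery (Fisher exact, chi-square, Welch t
    from summary statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
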