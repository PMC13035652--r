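Package: pbmasem
Title: Dichotomous Variables in Meta-Analytic Structural Equation Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for including a dichotomous variable in meta-analytic
    structural equation modeling (MASEM) of a three-variable mediation model.
    Implements six conversions from the standardized mean difference (Cohen's d)
    to the point-biserial correlation, closed-form population values of the
    mixture model induced by a dichotomous grouping variable as a function of
    its prevalence, a prevalence adjustment for the correlation between the
    continuous variables, a one-stage random-effects maximum-likelihood pooling
    engine for incomplete study-level correlation vectors, and a Monte Carlo
    simulation harness that evaluates the relative bias of each conversion
    under different sampling plans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    MASS
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    withr
Config/testthat/edition: 3
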