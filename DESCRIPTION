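Package: allomsur
Title: Additive Allometric Biomass Models via Seemingly Unrelated Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building component-wise tree biomass models for
    destructively sampled trees: six candidate log-linear allometric forms
    on diameter, height and crown radius, log-bias-corrected
    back-transformation (Baskerville correction factor), model comparison
    and selection by mean absolute prediction error and coefficient
    significance, and joint estimation of the selected component equations
    by iterated feasible generalized least squares (seemingly unrelated
    regression) so that predicted component biomasses sum exactly to the
    predicted total. Includes a seeded synthetic-population generator
    emulating age-grouped Casuarina equisetifolia inventory data, biomass
    allocation summaries with one-way ANOVA across age groups, and
    residual-normality diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
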