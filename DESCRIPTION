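Package: subpower
Title: Statistical Power of Subgroup Analyses in Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytic power for the pooled-effect test and the
    between-subgroup (moderator) Q-test in random-effects meta-analysis of
    standardized mean differences, with a required-number-of-studies solver,
    scenario grids over effect-size differences and unbalanced study
    allocation, and a seeded Monte-Carlo meta-analysis simulator that
    estimates empirical power and validates the analytic results. Power for
    the moderator test uses the noncentral chi-square distribution of the
    between-group homogeneity statistic; heterogeneity is specified as
    I-squared and converted to a variance inflation of the within-study
    sampling variances. A command-line interface exposes the calculators,
    the solver, the grid generator and the simulator.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    withr,
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
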