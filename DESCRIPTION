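Package: effortmob
Title: Effort-Based Decision-Making Under Acute Stress: Simulation, Model
    Fitting, and Bayesian Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying effort mobilization in forced-choice
    effort-versus-threat and effort-versus-reward paradigms. Provides the
    4x4 offer-grid task designs, four effort-discounting subjective-value
    families (linear, parabolic, hyperbolic, exponential) with a softmax
    choice rule, a synthetic-cohort generator with group-dependent model
    families and grip-force traces, two-step hierarchical model fitting
    (subject-level maximum likelihood followed by empirical-prior MAP
    re-fitting), AIC-based random-effects Bayesian model selection
    (Dirichlet posterior, exceedance probability, Bayes omnibus risk,
    protected exceedance probability), grip-force vigor metrics
    (overexertion and yank peak), permutation-based group contrasts, and a
    parameter/model recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
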