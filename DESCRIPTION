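Package: evmatch
Title: Invariant e-Values for Sharp Hypotheses via Median Matching Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Full Bayesian Significance Test (FBST) e-values for a scalar
    parameter of interest in the presence of nuisance parameters, built on
    objective matching priors derived from the cumulants of the (profile)
    score function. Provides median and mean (Firth-type) modified score
    equations and their bias-reduced estimators, median matching and
    predictive matching priors, pseudo-posterior construction on adaptive
    grids, exact one-dimensional e-values with tangential sets, first-order
    Wald- and score-type approximations, higher-order tail-area (modified
    likelihood root) approximations based on the Laplace marginal posterior,
    a rejection-ABC sampler, and experiment harnesses for null calibration
    of e-values. Includes a small library of parametric models (canonical
    exponential families, scale models, skew-normal shape, logistic
    regression under quasi-complete separation, bivariate regression) with
    seeded synthetic-data generators.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
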