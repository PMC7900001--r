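Package: outcomecast
Title: Internal Validation and Priority-Weighted Composite Prediction of
    Heterogeneous Adult Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and internally validating clinical
    prediction models of heterogeneous multi-facet adult outcomes from
    childhood and adolescent measures. Continuous outcomes are modeled with
    lasso regression (coordinate descent, penalty chosen by leave-one-out
    cross-validation) and ordinal outcomes with proportional-odds regression;
    predictive performance is optimism-corrected by nested leave-one-out
    cross-validation (R-squared) or by Harrell's bootstrap (generalized
    c-statistic). A joint outcome model with correlated residuals (probit
    latent scale for ordinal outcomes) yields 95 percent prediction intervals
    for single outcomes and for composite outcomes weighted by priorities
    elicited from parents or individuals. A seeded synthetic-cohort generator
    with known ground truth (longitudinal shared-factor predictors,
    configurable population R-squared, cross-outcome residual correlation,
    missingness-at-random dropout) makes every stage testable without access
    to sensitive cohort data. Includes k-nearest-neighbor imputation,
    scale pro-rating, minimum sample-size (shrinkage) criteria, and
    report/figure generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    MASS,
    rlang,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    mvtnorm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
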