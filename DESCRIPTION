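Package: scorebias
Title: Bias of Test-Score, Plausible-Value and SEM Approaches to Latent
    Predictors in Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte-Carlo machinery for studying how different ways of
    scoring a multi-item ordinal scale propagate measurement error into
    multiple regression. Simulates a standard-normal latent skill measured
    by 4-12 congeneric five-category items together with a correlated
    covariate and continuous outcomes; scores the items by standardized
    mean scores, regression factor scores, and generalized partial credit
    model based WLE, EAP and posterior-mode (EBM) estimates; generates
    plausible values from a latent-regression conditioning model pooled by
    Rubin's rules; and fits the full structural equation model by
    normal-theory maximum likelihood. Summarizes percent bias of the skill
    and covariate regression coefficients over a 36-cell factorial design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
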