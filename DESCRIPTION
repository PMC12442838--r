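Package: emadiff
Title: Drift Diffusion Decomposition of Response Times in Ecological
    Momentary Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes item-level response times and binary responses from
    ecological momentary assessment (EMA) surveys into per-occasion drift
    rate and boundary separation using a D-diffusion item response theory
    model built on the two-boundary Wiener first-passage process. Provides
    the preprocessing rules for EMA response-time data (midpoint
    dichotomization, response-time capping, removal of occasions without
    response-time variation, activity coding), marginal maximum-likelihood
    estimation of item parameters with expected a-posteriori occasion
    scores, multilevel reliability (intraclass correlations), latent
    covariate two-level regression and correlations, 1-1-1 and 2-1-1
    multilevel mediation with Monte-Carlo intervals, negative exponential
    practice-effect growth curves, and a synthetic EMA data generator with
    exposed ground truth for recovery studies.
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
    glmmTMB,
    jsonlite,
    lme4,
    mvtnorm,
    purrr,
    Rcpp,
    readr,
    rlang,
    statmod,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
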