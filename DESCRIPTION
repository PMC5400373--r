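Package: invasionabc
Title: Invasion-Route Inference from Microsatellite Data by Approximate
    Bayesian Computation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to reconstruct the introduction routes of invasive
    populations from multi-locus microsatellite genotypes. Competing
    invasion scenarios (single-source introductions and two-source
    admixtures, with founding bottlenecks and unsampled ghost
    populations) are declared as backward-time demographic event lists,
    simulated under a structured coalescent with a generalized stepwise
    mutation model, and summarized with the standard one-, two- and
    three-population microsatellite statistic catalog. Model choice is
    performed by approximate Bayesian computation with random forests
    (classification votes, out-of-bag prior error rate, posterior
    probability via a secondary error-regression forest) and by a
    standard rejection method with polychotomous logistic regression on
    linear discriminant axes. Parameters such as bottleneck severity and
    admixture rates are estimated by local linear regression on
    logit-transformed draws, and fitted scenario-posterior combinations
    are checked with posterior predictive p-values under false discovery
    rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    nnet,
    ranger,
    arrow,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    parallel
Config/testthat/edition: 3
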