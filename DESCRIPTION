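Package: bdnn
Title: Bayesian Birth-Death Neural Networks for Fossil Diversification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Inference of lineage- and time-specific speciation and
    extinction rates from fossil occurrence data using a Bayesian
    birth-death process whose rates are emitted by small unsupervised
    neural networks over time, traits, phylogenetic eigenvectors, and
    environmental time series. Includes the Metropolis-Hastings sampler
    over origination/extinction times, preservation parameters and
    network weights; a preservation model with among-lineage rate
    heterogeneity; explainable-AI tools (partial dependence, permutation
    importance, SHAP values, consensus ranking) to identify the
    predictors of rate variation; a forward-time simulator of nine
    benchmark diversification scenarios; and evaluation metrics
    (median absolute relative error, credible-interval coverage, and a
    calibrated coefficient-of-variation test for rate constancy).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    optparse,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
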