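Package: cdmi
Title: Cognitive Diagnosis Models with Multiple-Imputation Reliability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of the DINA and G-DINA cognitive diagnosis models by
    marginal maximum likelihood (EM), posterior attribute-profile inference and
    EAP classification, and classification-accuracy reliability indices (tau and
    tau_k). Includes a nonparametric-bootstrap multiple-imputation correction
    that integrates model-parameter uncertainty out of the posterior
    distributions, yielding reliability estimates that are not inflated in small
    samples, together with a Monte Carlo simulation harness (attribute
    generators, monotone item-parameter generators, built-in Q-matrices,
    condition runner, bootstrap stability and subsampling studies).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
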