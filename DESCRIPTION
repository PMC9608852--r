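Package: envpls
Title: Predicting Unobserved Environments in Multi-Environment Trials
    with Partial Least Squares and Bayesian GBLUP
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genomic prediction of entire unobserved
    environments in plant breeding trials. Implements partial least
    squares (PLS) regression on design matrices augmented with the
    symmetric square roots of genomic and environmental relationship
    matrices, a Bayesian GBLUP reaction-norm benchmark with
    genotype-by-environment interaction modelled through a Kronecker
    covariance, a leave-one-environment-out evaluation protocol with
    nested cross-validation for latent-variable selection, marker
    quality control, and a multi-environment trial simulator for the
    underlying variance-component model. Accuracy is reported as
    normalized root mean squared error and relative efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
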