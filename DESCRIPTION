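Package: AddDomGS
Title: Additive-Dominance Genomic Prediction with Ridge, Lasso and
    Bayesian Shrinkage Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for genome-wide selection
    under additive-dominance genetic models. Provides a forward simulator
    of a composite breeding population with controlled linkage
    disequilibrium and full-sib family structure; the classical W/S
    marker parameterization with additive and dominance genomic
    relationship matrices and their pedigree counterparts; REML/G-BLUP
    and a unified Gibbs sampler covering Bayesian ridge regression,
    Bayesian Lasso variants and Student-t shrinkage priors for marker
    effects; deterministic accuracy formulas and a
    training/validation protocol for comparing methods; and the
    decomposition of genomic heritability and accuracy into linkage
    disequilibrium, co-segregation and pedigree-relationship components.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
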