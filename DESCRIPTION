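Package: tRNAcif
Title: Class-Informative Features of tRNA Gene Complements for Genome
    Phyloclassification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates clade-specific tRNA function logos (Gorodkin heights
    of class-informative features) from Sprinzl-coordinate-aligned tRNA gene
    complements, scores genome tRNA gene complements against them, and
    trains and validates a multilayer-perceptron phyloclassifier on the
    resulting score vectors. Includes leave-one-out cross-validation with
    leakage-free logo re-estimation, permutation null testing, alignment
    site bootstrapping, leave-clade-out model variants, oversampling
    balance, one-vs-all confusion metrics, and a synthetic data generator
    that plants clade-specific class-informative features for end-to-end
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'tRNAcif-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'counts.R'
    'filters.R'
    'io.R'
    'logos.R'
    'mlp.R'
    'partition.R'
    'pipeline.R'
    'robustness.R'
    'scoring.R'
    'synthetic.R'
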