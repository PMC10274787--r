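Package: glucodyn
Title: Glucose-Exposure Time-Course Analysis of Pancreatic Islet Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell RNA-seq time courses of
    pancreatic islets exposed to low and high glucose. Provides a seeded
    synthetic-data generator with planted effects, quality-control filters and
    log-CP10K normalization, marker-based cell-type annotation with a
    classifier-validated clustering-resolution rule, nearest-neighbor
    interpolated time, a two-part hurdle differential-expression engine for
    discrete and continuous time/glucose designs, Dirichlet-process
    Gaussian-process consensus clustering of temporal expression profiles into
    modules, hypergeometric gene-set enrichment, and polygenic-priority
    candidate-gene scoring with a permutation null.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    nnet,
    MASS,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
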