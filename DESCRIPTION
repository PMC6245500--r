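Package: metaboAge
Title: Individual-Based Metabolic Modelling of Transcriptomic and Metabolic Age
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds individual-specific metabolic models by constraining a
    genome-scale metabolic model with each individual's normalised gene
    expression profile, derives fluxomic profiles through a lexicographic
    (bilevel) flux balance analysis with biomass as primary and ATP
    maintenance as secondary objective, and runs a set of ageing statistics
    on the resulting poly-omic data: an effect-size-weighted transcriptomic
    age predictor, age-based silhouette comparison of transcriptomic versus
    fluxomic clusterings, eigenvalue-weighted principal-component
    contributions per age group, and an elastic-net metabolic age predictor.
    Includes a synthetic-cohort generator with planted age effects so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    glmnet,
    jsonlite,
    yaml,
    xml2,
    S4Vectors,
    IRanges,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
biocViews: Metabolomics, Transcriptomics, Network, Regression, Clustering
Config/testthat/edition: 3
RoxygenNote: 7.3.3
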