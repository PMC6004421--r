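Package: pathsem
Title: Differential Expression-Variance Analysis and Multigroup Structural
    Equation Modeling of Signaling Pathways
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing gene-expression variance between two groups
    of samples (e.g., case and control), testing pathway enrichment of
    variance signals by over-representation and gene-set statistics, and
    modeling pathway wiring by covariance-structure maximum-likelihood
    structural equation models. Pathway diagrams with multi-gene (complex)
    nodes are expanded into all alternative single-gene models, each fitted
    by multigroup SEM with covariate equations constrained equal across
    groups; models are screened by identifiability, path significance and
    RMSEA, the best model is selected by CFI, and per-edge between-group
    Wald tests report interactions whose strength differs between groups.
    A truth-known synthetic-data generator with the same structural model
    supports calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    igraph,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
biocViews: GeneExpression, Pathways, GraphAndNetwork, StructuralEquationModels
Config/testthat/edition: 3
RoxygenNote: 7.3.3
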