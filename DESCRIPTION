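Package: isescreen
Title: Iterative Stochastic Elimination Models for Ligand-Based Virtual
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds ligand-based activity classifiers as ensembles of
    five-descriptor-range "filters" selected by Iterative Stochastic
    Elimination (ISE): candidate descriptor ranges are scored by the
    Matthews correlation coefficient against property-matched decoys,
    poorly performing ranges are eliminated stochastically until the
    remaining combinations can be enumerated exhaustively, and the
    top-ranked filters score arbitrary molecules on a [-1, +1] index for
    virtual screening. Includes the surrounding protocol: bioactivity
    curation, applicability-domain decoy selection, stratified and
    leave-one-out cross-validation, enrichment/ROC/diversity reports,
    Y-randomization, and drug-target interaction matrices, plus a
    synthetic fixture generator with planted ground-truth filters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    Rcpp,
    ChemmineR,
    ChemmineOB
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
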