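Package: graphdock
Title: Gated Graph Attention Scoring of Protein-Protein Docking Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality assessment of pairwise protein docking models (decoys).
    The interface region of a two-chain complex is represented as a pair of
    heavy-atom graphs, one restricted to covalent bonds and one augmented with
    Gaussian-weighted cross-molecular edges; both are processed by shared
    gate-augmented graph attention layers whose embeddings are subtracted to
    isolate the intermolecular signal, and a fully connected head returns the
    probability that the decoy is of acceptable quality under the CAPRI
    criteria.  Also provides CAPRI interface metrics (iRMSD, lRMSD, fnat) with
    quality classification, class-balanced training with Adam, decoy ranking
    and hit-rate evaluation, and a synthetic rigid-body decoy generator for
    desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml,
    pROC,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
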