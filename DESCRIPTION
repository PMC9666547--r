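Package: dimernet
Title: Inter-Chain Residue Distance Prediction for Protein Dimers with an
    Attention-Powered Residual Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts inter-chain residue-residue distance distributions
    (distograms) for homodimers and heterodimers from monomer structures,
    multiple sequence alignments and co-evolutionary features.  Implements
    the full pipeline as a trainable library: feature assembly into an
    L x L x 186 tensor (intra-chain Cb distance channel, coupling-score and
    row-attention channels, tiled PSSM channels), a deep 2D residual network
    with Maxout input reduction, row/column/instance (RCIN) normalization,
    squeeze-and-excitation channel attention and spatial attention, dual
    42-bin softmax distogram heads, masked inter-chain cross-entropy training
    with a two-phase Adam/SGD schedule, inference-time ensemble and two-order
    (AB/BA) averaging, contact-probability conversion and ranking, and the
    standard contact-evaluation metrics (top-k precision, accuracy order,
    accuracy rate, AUC).  A synthetic dimer generator with plantable
    co-evolutionary signal makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
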