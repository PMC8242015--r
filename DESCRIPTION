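Package: rmnet
Title: Multi-Label Attention Networks for RNA Modification Site Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated prediction and interpretation of twelve widely occurring
    RNA modifications (m6A, m1A, m5C, m5U, m6Am, m7G, Psi, I, Am, Cm, Gm, Um)
    from primary RNA sequence. Implements a multi-label neural network with an
    LSTM encoder and one additive (Bahdanau) attention head per modification,
    k-mer word2vec sequence embeddings trained in-package, imbalance-aware
    losses (online hard example mining, uncertainty weighting, focal loss,
    effective-number class weights), integrated-gradients attribution, motif
    mining with density-based clustering, cross-modification association
    analysis, rank-based significance bounds, and a synthetic-corpus generator
    with planted motifs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap
Config/testthat/edition: 3
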