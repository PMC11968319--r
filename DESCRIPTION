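Package: biowords
Title: Peptide Bioactivity Classification with Biological-Word Embeddings
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies short peptides (for example antiviral peptides) from
    primary sequence alone. Sequences are decomposed into overlapping k-mer
    "biological words" (1mers for loop residues, 4mers approximating one
    alpha-helix turn), embedded with Word2Vec models (CBOW or Skip-gram,
    exact-softmax training implemented in the package), and classified by a
    dual-channel neural network: a 1D-CNN plus Transformer-encoder channel for
    the 1mer view and a Transformer-only channel for the 4mer view, fused by a
    dense head. Includes dataset assembly filters for peptide FASTA files,
    stratified splits and cross-validation, confusion-matrix and ranking
    metrics (ACC, SN, SP, MCC, AUROC), architecture variants (BiLSTM, TCN,
    LSTM, GRU, BiGRU) and ablation grids, attention-based position
    attribution, position-wise residue enrichment tables, and a synthetic
    motif-implantation data generator so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
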