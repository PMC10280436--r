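Package: tsspredict
Title: Transcription Start Site Datasets, String-Kernel SVMs and Sequence Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds labeled transcription-start-site (TSS) datasets from a
    genome and a transcript annotation (positive windows anchored on annotated
    TSS positions, semi-synthetic negative windows sampled inside transcripts,
    chromosome-based train/validation/test splits), computes weighted-degree
    string kernels and RBF kernels, trains support vector machines with a
    cascade scheme for large datasets, trains five sequence neural-network
    architectures (CNN, LSTM, BLSTM and CNN/LSTM hybrids) on one-hot encoded
    windows, and evaluates classifiers with an imbalance-aware metric suite
    (accuracy, binary cross-entropy, precision/recall/F1, sensitivity,
    specificity, AUC-ROC). Includes a synthetic-genome fixture generator with
    a planted, learnable TSS motif so the full pipeline runs without external
    downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    kernlab,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
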