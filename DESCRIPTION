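Package: migcn
Title: Attention-Based BiLSTM-GCN Decoding of Four-Class Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for four-class motor-imagery EEG decoding:
    reads EDF recordings with event annotations, slices 4-s trials into 0.4-s
    64x64 segments, learns per-segment features with a bidirectional LSTM and
    temporal attention pooling, builds a feature-correlation graph (Pearson
    matrix, absolute-value adjacency, normalized Laplacian), and classifies
    with a Chebyshev spectral graph-convolutional network using Graclus
    multilevel coarsening and balanced-binary-tree max pooling. Includes a
    synthetic motor-imagery EEG generator, repeated-holdout validation, and
    multiclass evaluation (overall accuracy, Cohen's kappa, macro
    precision/recall/F1, micro-averaged ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
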