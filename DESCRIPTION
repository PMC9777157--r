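Package: kneedhl
Title: Deep Hybrid Learning for Radiographic Knee Osteoarthritis Grading
Version: 0.1.0
Authors@R: person("kneedhl", "developers", role = c("aut", "cre"),
    email = "kneedhl@example.org")
Description: Grades knee osteoarthritis severity on the Kellgren-Lawrence
    (KL) ordinal scale from plain radiographs with a deep hybrid learning
    pipeline: a compact five-convolution CNN trained from scratch on
    112x112 CLAHE-enhanced images, whose 200-dimensional penultimate
    features are MinMax-scaled, reduced by PCA at 99 percent explained
    variance and classified by an RBF-kernel support vector machine
    (DHL-I); and transfer-learned variants that freeze the convolutional
    blocks and fine-tune a new 512/256 fully connected head for coarser
    4/3/2-class KL groupings before the same feature-extraction head
    (DHL-II). Includes a synthetic knee-radiograph phantom generator
    (joint-space narrowing, osteophytes, subchondral sclerosis) so the
    whole pipeline is testable without clinical data, plus confusion
    matrix, per-class and macro metrics, ROC/AUC, and a command line
    interface for reproducible experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
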