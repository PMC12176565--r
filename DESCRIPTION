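Package: pcgcbam
Title: Heart Sound Classification with Convolutional Block Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phonocardiogram (PCG) classification pipeline: segmentation of
    heart-sound recordings into fixed 5-second windows, log-power STFT
    spectrogram images, a compact convolutional neural network with
    configurable Convolutional Block Attention Module (CBAM) placement
    (channel attention followed by spatial attention), a training harness
    with Adam, plateau learning-rate decay and early stopping, stratified
    grouped cross-validation, confusion-matrix metrics and ROC/AUC, and
    t-SNE class-separability statistics. Includes a seeded synthetic
    heart-sound generator (S1/S2 transients plus optional systolic murmur)
    so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    png,
    jsonlite,
    EBImage,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
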