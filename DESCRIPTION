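Package: pdscreen
Title: Speech and Handwriting Screening Pipelines for Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Desk-scale learning and optimization toolkit for Parkinson's
    disease screening from voice recordings and drawn-shape images.
    Provides multi-duration voice segmentation, a 281-column acoustic
    feature schema (MFCC, mel-spectrogram, chroma, spectral, tonnetz),
    time-frequency image rendering, class equalization by augmentation,
    grid-searched scaler/variance-threshold/classifier pipelines, the
    Aquila Optimizer metaheuristic with a 14-dimensional CNN and
    augmentation hyperparameter codec, a small trainable convolutional
    backbone, extended classification metrics, and two-test score fusion
    for patient-level diagnosis. Synthetic audio and drawing generators
    emulate the shape of the public datasets so every pipeline stage can
    be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr
Suggests:
    FNN,
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
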