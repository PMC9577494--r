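Package: emofuse
Title: Multi-Modal Physiological Emotion Recognition with Feature-Level Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for binary arousal/valence emotion recognition from
    multi-modal peripheral physiology (ECG, electrodermal activity,
    respiration). Provides a synthetic trial generator with exact ground
    truth, signal preprocessing (zero-phase FIR band-pass filtering,
    Hamilton-style QRS detection, sparse-deconvolution EDA decomposition,
    breath-cycle segmentation, per-subject baseline compensation), a
    58-feature extractor (47 heart-rate-variability features plus 4 EDA and
    7 respiration features), classical machine-learning baselines evaluated
    on fully balanced subsets, and a multi-input one-dimensional
    convolutional neural network trained from scratch with Adam and
    cross-entropy, alongside single-input variants for fusion comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    e1071,
    randomForest,
    class,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
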