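Package: mnvit
Title: Lightweight Convolution-Transformer Networks for Micronucleus Image
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and audits MobileViT-MN, a lightweight hybrid
    convolution/transformer classifier for two-class cell-micronucleus
    images. Provides squeeze-and-excitation and normalization-based channel
    attention, a depthwise/pointwise decomposition of the standard
    convolutions inside MobileViT blocks, a factory for the full ablation
    grid of attention placements and transformer depths with exact trainable
    parameter and multiply-accumulate audits, a seeded synthetic
    micronucleus image generator, an imbalance-aware dataset pipeline
    (stratified splitting, rotation/flip/scale augmentation, minority
    oversampling with majority downsampling), a native training loop with
    transfer-learning weight loading, and balanced-accuracy/F1/ROC-AUC
    evaluation. The whole workflow runs end-to-end on synthetic microscopy
    images without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
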