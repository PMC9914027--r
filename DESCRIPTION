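Package: dermshuffle
Title: Lightweight Channel-Shuffle CNN with Squeeze-and-Excitation
    Attention for Seven-Class Dermoscopy Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a parameter-budgeted convolutional neural network
    for classifying pigmented skin lesions into the seven standard
    dermoscopy classes (AK, BCC, BKL, DF, MEL, NV, VASC). The architecture
    combines ShuffleNet-style units (channel split, depthwise-separable
    convolutions, channel shuffle) with squeeze-and-excitation channel
    attention and GELU activations, and is assembled under a 1.9 million
    trainable-parameter budget. The package also provides a manifest-driven
    data pipeline with centroid region-of-interest cropping and a
    class-balancing augmentation engine, a synthetic dermoscopy image
    generator for fully reproducible testing, per-class and macro
    evaluation metrics (accuracy, sensitivity, specificity, precision,
    F1, Matthews correlation), a seeded training harness with stratified
    k-fold cross-validation, and Grad-CAM interpretability maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
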