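Package: sonosiam
Title: Few-Shot Siamese Screening of Ultrasound Phantoms with INT8
    Post-Training Quantization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Metric-learning toolkit for screening grayscale ultrasound-like
    images when abnormal examples are scarce. Provides a synthetic phantom
    generator with controllable class imbalance and source-specific nuisance
    artifacts, abnormal-only augmentation, SMOTE/SMOTE-NC oversampling for
    tabular health records, stratified mixed-source k-fold splits, a
    shared-weight convolutional Siamese encoder trained with a margin-based
    contrastive loss plus weighted multi-task classification heads under
    three-stage curriculum pair sampling, and a from-scratch post-training
    INT8 quantization engine (batch-norm folding, min-max/percentile/KL
    activation calibration, symmetric per-channel weights, affine activations,
    int32 accumulation) with integer-simulated inference and size accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    class,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
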