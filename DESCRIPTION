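Package: histoperm
Title: Class-Preserving View Permutation for Representation Learning on
    Histology Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Self-supervised representation learning for weakly labeled
    histology patches using joint-embedding architectures (BYOL-, SimCLR-
    and VICReg-style objectives) with a class-preserving permutation of one
    augmented view: for the labeled fraction of each mini-batch, the second
    view of a patch is replaced by a view of a different patch of the same
    class via a bijective within-class shuffle. Includes whole-slide-image
    patch extraction with Lanczos downsampling and per-class overlap
    selection, the two-view augmentation pipeline, pretraining with the
    LARS optimizer under a warmup-cosine schedule, linear-probe evaluation
    on frozen encoders, patch- and slide-level metrics with average-pooling
    aggregation, and a deterministic pseudo-histology slide generator for
    fully self-contained experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
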