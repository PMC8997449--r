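Package: dermafuse
Title: Multimodal Recognition of Pigmented Skin Lesions with Morphological Hair Removal
Version: 0.1.0
Authors@R:
    person("dermafuse", "maintainers", email = "dermafuse@example.org", role = c("aut", "cre"))
Description: Toolkit for multimodal classification of dermoscopic images of
    pigmented skin lesions. Provides a morphological hair-identification and
    removal preprocessor (per-channel grayscale closing, thresholded residual,
    dilation and Laplace-equation inpainting), one-hot encoding of patient
    metadata (sex, anatomic site, five-year age group), affine augmentation and
    stratified train/validation splitting, a small image+metadata fusion
    classifier trained with stochastic gradient descent, and evaluation
    statistics (confusion matrices, benign/malignant grouping, ROC/AUC,
    McNemar's paired test). A synthetic-fixture generator produces
    dermoscopy-like lesion images with hair overlays and ground-truth masks so
    the full pipeline is testable without any image archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
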