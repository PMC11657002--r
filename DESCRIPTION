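Package: spixelseg
Title: Weakly Supervised Brain Tumor Segmentation via Deep Superpixel
    Generation and Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains brain-tumor segmentation models from binary image-level
    labels only. A convolutional classifier is trained on tumor-presence
    labels; randomized input-sampling (RISE) occlusion saliency converts the
    classifier into undersegmented positive/negative localization seeds; a
    deep superpixel-generation network and a superpixel-clustering network
    are then trained jointly against a superpixel compactness loss plus a
    seeding loss, and their soft-clustered output is thresholded into tumor
    masks. Includes multimodal MRI slice preprocessing (foreground crop,
    percentile clipping, min-max scaling, axial slicing, patching), a
    synthetic multimodal lesion phantom generator, evaluation metrics (Dice
    with smoothing, 95th-percentile Hausdorff distance, undersegmented
    Dice), and a compact tape-based autodiff/CNN core so the whole pipeline
    runs on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tibble,
    yaml,
    rlang,
    ggplot2,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    jsonlite
Config/testthat/edition: 3
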