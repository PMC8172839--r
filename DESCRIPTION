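Package: wsikit
Title: Whole-Slide Image Segmentation and Downstream Pathology Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A patch-based pipeline for the segmentation and analysis of
    gigapixel whole-slide histopathology images (WSI), exercisable at desk
    scale on synthetic pyramidal slides. Provides tissue masking by Otsu
    thresholding of the HSV saturation channel with morphological cleanup,
    class-balanced training-patch sampling with coordinate perturbation and
    colour/geometric augmentation, a hybrid Dice plus cross-entropy
    segmentation loss, a predictor/ensemble contract with posterior
    averaging, overlap-averaged heatmap stitching, test-time-augmentation
    (aleatoric) and across-model (epistemic) uncertainty maps, lymph-node
    metastasis typing and pN staging from heatmap-derived morphological
    features, and convex-hull based viable tumour burden estimation. A
    deterministic synthetic H&E-like slide generator with known ground
    truth makes every stage testable without slide downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    randomForest,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
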