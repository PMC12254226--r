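Package: amyloidCRF
Title: Amyloid Detection and Quantification on Congo Red Fluorescence
    Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies cardiac amyloid deposits on Congo red
    fluorescence whole-slide images. A Texas Red (TRITC) channel capturing
    dye fluorescence is combined with a "scramble" autofluorescence channel
    of the same physical slide; subtracting the two isolates amyloid signal,
    which is binarized into a deposit mask, measured as amyloid burden
    (deposit area over tissue area), and transferred onto the aligned
    brightfield image as polygon annotations. The package also provides a
    synthetic slide generator with ground-truth masks for the four cardiac
    deposition geometries, tile extraction with weak labels, case-level
    nested cross-validation of a small convolutional tile classifier and a
    per-pixel segmenter with Grad-CAM explainability, slide-level
    probability aggregation, and the full evaluation-metric suite
    (confusion-matrix metrics, AUC-ROC, IoU, Dice, Cohen's kappa,
    concordance, Spearman correlation, Cohen's d, median/IQR).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
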