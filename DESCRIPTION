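Package: lesionfuse
Title: Multi-Path 2.5D Convolutional Segmentation of Stroke Lesions in Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Segments stroke lesions in skull-stripped, atlas-aligned
    T1-weighted brain MRI (optionally paired with FLAIR) with an ensemble of
    nine 2D dual-encoder U-networks, one per combination of slicing plane
    (axial, sagittal, coronal) and intensity normalization scheme, whose
    binarized predictions are merged into a single 3D mask by a small 3D
    convolutional post-processor trained with a two-channel soft-Dice loss.
    Includes the evaluation machinery (Dice coefficient, lesion-size
    stratification, Wilcoxon rank-sum comparisons, k-fold and cross-study
    harnesses) and a synthetic phantom generator so the full pipeline can be
    trained and validated at desk scale without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
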