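Package: lungnodenet
Title: 3D Residual U-Net Segmentation and 3D ResNet50 Diagnosis of Lung
    Nodules on CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a two-stage lung-nodule CAD
    pipeline for volumetric CT: morphological lung-parenchyma extraction,
    resampling and subcase geometry, a 3D residual U-Net trained with a
    dynamically switched binary cross-entropy/Dice loss for nodule
    segmentation, and a modified 3D ResNet50 (no max-pooling, reduced
    kernels, strided downsampling) for benign/malignant classification of
    16x48x48 nodule regions of interest. Includes a synthetic CT phantom
    generator with known lung and nodule masks so every stage is testable
    without clinical data, the full Dice/BCE/NLL loss family with
    documented gradients, segmentation metrics stratified by nodule size,
    confusion-matrix metrics and ROC/AUC, NIfTI and basic DICOM input, and
    deterministic CPU training loops for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
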