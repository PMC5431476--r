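Package: retmodal
Title: Multimodal Quantification of Hyper-Reflective Foci and Hard Exudates
    in Diabetic Retinopathy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Joint analysis of hyper-reflective foci (HRF) in spectral-domain
    optical coherence tomography (SD-OCT) volumes and hard exudates (HE) in
    color fundus photographs of eyes with diabetic retinopathy. Provides
    retinal layer segmentation by dynamic programming, layer-bounded HRF
    detection with adaptive thresholding and region growing, multiscale
    CIELab saliency segmentation of hard exudates, landmark-based
    fundus-to-en-face registration, five per-eye lesion features (area,
    amount, distance to fovea, axial altitude, reflectivity), agreement
    statistics between the two modalities, and NPDR-vs-PDR severity
    classification with a leave-one-out RBF support vector machine. A
    phantom generator produces paired synthetic OCT/fundus cases with full
    ground truth so every stage can be validated without patient data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    png,
    e1071,
    EBImage,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
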