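Package: hsifuse
Title: Spectrum-Image Fusion for VNIR-SWIR Hyperspectral Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying hyperspectral reflectance cubes of sliced
    plant material by origin or class. Covers white/dark reflectance
    calibration and ENVI input/output, automatic per-slice region-of-interest
    segmentation, spectral preprocessing (SNV, MSC, Savitzky-Golay smoothing
    and derivatives), effective-wavelength selection by the successive
    projections algorithm, gray-level co-occurrence and run-length texture
    statistics, three-dimension feature-level fusion of spectral and image
    blocks across VNIR and SWIR camera ranges, PLS-DA (NIPALS) and RBF-SVM
    classification with repeated stratified cross-validation and ROC/AUC
    evaluation, and pixel-wise classification maps. A seedable synthetic
    scene generator with known class structure supports end-to-end testing
    and method studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    signal,
    e1071,
    igraph,
    jsonlite,
    yaml,
    png,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'envi.R'
    'spa.R'
    'fusion.R'
    'svm.R'
    'plsda.R'
    'evaluate.R'
    'hsifuse-package.R'
    'hypercube.R'
    'preprocess.R'
    'segmentation.R'
    'maps.R'
    'texture.R'
    'synthetic.R'
    'pipeline.R'
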