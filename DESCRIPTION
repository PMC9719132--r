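Package: viascreen
Title: Image Analysis Pipeline for Smartphone-Based VIA Cervical Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies cervix photographs taken after acetic-acid application
    (VIA, visual inspection with acetic acid) as positive or negative for
    acetowhite precancerous lesions. Implements the full screening pipeline:
    specular-reflection detection and inpainting via a multi-channel feature
    image and standard-deviation filter, cervix region-of-interest detection
    with a spherical-covariance Gaussian mixture model on the Ra space
    (radial distance plus CIE-Lab a*), a fixed 75-feature colour and texture
    panel (colour statistics, GLCM, NGTDM, GLSZM, DWT, LBP), correlation-based
    multicollinearity pruning with z-score normalisation, and cross-validated
    selection among nine classifier families under a precision-at-recall
    objective with thresholded prediction. Ships a seeded synthetic cervix
    scene generator with ground-truth masks so every stage is testable
    without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    png,
    jsonlite,
    igraph,
    EBImage,
    xgboost,
    randomForest,
    ranger,
    e1071,
    rpart,
    class
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    withr
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'classifiers.R'
    'cli.R'
    'config.R'
    'features-color.R'
    'features-glcm.R'
    'features-texture.R'
    'features-transform.R'
    'features.R'
    'model.R'
    'preprocess.R'
    'roi.R'
    'selection.R'
    'synthetic.R'
    'utils-image.R'
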