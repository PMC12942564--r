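Package: hematochron
Title: Hematoma Age Estimation from Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the age of hematomas (bruises) from
    hyperspectral reflectance images. Provides a longitudinal hematoma
    phantom simulator with physiologically motivated chromophore kinetics
    (hemoglobin decay, bilirubin rise and fall, contrast fading),
    radiometric white/dark reference normalization, spectral-angle lesion
    segmentation and patch extraction, a spectral-spatial convolutional
    network regressor and a Lasso baseline on spatially averaged spectra,
    leave-one-subject-out cross-validation with stage-wise error reporting,
    and consensus band-importance analysis (SmoothGrad plus occlusion
    sensitivity) for reduced-band acquisition design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
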