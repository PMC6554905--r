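Package: grasshsi
Title: Hyperspectral Imaging Chemometrics for Ryegrass Forage Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for predicting forage-quality attributes of perennial
    ryegrass from line-scan hyperspectral images (550-1700 nm, 235 bands):
    ENVI cube input/output, white/dark radiometric calibration, reflectance
    thresholding for plant segmentation, standard normal variate (SNV)
    preprocessing, partial least squares regression (NIPALS) with Monte Carlo
    cross-validation and Adjusted Wold latent-variable selection, CARS and
    VIP wavelength selection, a multi-method regression comparison harness,
    per-pixel trait mapping, and pseudostem-versus-blade composition
    analyses. Includes a synthetic scene generator that emulates the
    instrument geometry, tissue-specific spectral signatures, attribute
    distributions and lighting gradients of the study design, so the whole
    pipeline is testable end to end without plant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    e1071,
    kernlab,
    randomForest,
    png
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
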