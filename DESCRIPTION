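Package: liverhsi
Title: Liver Viability Scoring from Hyperspectral Images with
    Spatio-Spectral Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for scoring liver viability from intraoperative
    hyperspectral imaging. Reads and writes hyperspectral reflectance cubes
    (ENVI and a package-native archive), converts reflectance to absorbance,
    computes tissue oxygen saturation (StO2) and near-infrared perfusion index
    maps from absorbance spectra, and classifies each pixel with two small
    3D spatio-spectral convolutional networks: one segmenting the organ, one
    characterising perfused versus ischemic tissue. Includes post-segmentation
    morphological filtering, a per-image viability score, leave-one-subject-out
    cross-validation, correlation statistics against biomarkers, and a
    synthetic phantom generator emulating hepatic-artery-occlusion
    ischemia-reperfusion experiments for self-contained evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pROC,
    png,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
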