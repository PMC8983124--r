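Package: ferretlung
Title: Quantitative Lung Phenotyping for Ferret Models of Antitrypsin
    Deficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable implementations of the quantitative phenotyping
    pipeline used to characterize emphysema in ferret models of alpha-1
    antitrypsin deficiency: quantitative-CT emphysema scoring (percent
    low-attenuation area at Hounsfield thresholds, with threshold lung
    segmentation, region-growing airway removal and 3D mask cleanup),
    forced-expiration spirometry (FEV_x, FVC, FEV_x:FVC calibration),
    multistroke inspiratory capacity, Salazar-Knowles pressure-volume
    compliance fitting, alveolar airspace morphometry (surface-area to
    perimeter ratios via a calibrated Crofton estimator), neutrophil
    elastase inhibition AUC, and longitudinal random-intercept mixed
    models of lung function versus age.  Every input the pipeline
    consumes can be simulated with known ground truth, so the whole
    chain is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    minpack.lm,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    pracma,
    EBImage,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
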