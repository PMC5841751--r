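Package: ntra
Title: Nonlinear Trimodal Regression Analysis of CT Muscle Radiodensity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies skeletal muscle quality from mid-thigh computed
    tomography cross-sections by modelling the entire Hounsfield-unit (HU)
    pixel distribution as a sum of two skewed and one standard Gaussian
    component (fat, loose connective / water-equivalent tissue, muscle),
    fitted by bound-constrained nonlinear least squares on smoothed
    128-bin histograms. Also computes the standard CT comparison metrics
    (fat and lean cross-sectional area, mean lean attenuation), discretizes
    clinical covariates by exact one-dimensional k-means with Sturges'
    formula for class selection, and correlates imaging parameters with
    covariates through binned linear and multiple regression. Includes a
    synthetic-cohort generator with planted parameter-covariate couplings
    that provides ground truth for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
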