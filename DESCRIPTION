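Package: thermaheal
Title: Predicting Venous Leg Ulcer Healing from Thermal Image Texture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for computerised prognosis of venous leg ulcer
    healing from a single week-0 pseudo-colour thermal image. Images are
    pre-processed (logo in-fill, greyscale conversion, min-max
    normalisation, Otsu masking with morphological enhancement, wound-bed
    extraction), characterised by 19 grey-level co-occurrence matrix
    (GLCM) texture features, screened by Mann-Whitney U tests with effect
    sizes, reduced to three principal components, and classified by a
    small feedforward neural network whose hidden-layer width is selected
    by the Bayesian evidence framework (Laplace approximation with weight
    decay). Includes a synthetic pseudo-colour thermal wound generator so
    every stage is testable without patient data, and a repeated-holdout
    evaluation harness reporting sensitivity, specificity, ROC and AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
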