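Package: tsmammo
Title: Temporal Subtraction of Sequential Mammograms for
    Microcalcification Detection and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and BI-RADS-style classification of breast
    microcalcifications from pairs of temporally sequential mammograms.
    Implements preprocessing (normalisation, breast segmentation, gamma
    correction), non-rigid Demons registration of the prior view onto the
    recent one, temporal subtraction with contrast-ratio and
    lesion-removal accounting, candidate segmentation by range filtering
    and morphology, a 96-feature extractor (shape, first-order intensity,
    and grey-level co-occurrence texture), feature selection, and
    two-round patient-grouped classification with leave-one-patient-out
    cross-validation. A synthetic phantom generator provides sequential
    image pairs with known ground truth so the full pipeline can be
    exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    nnet,
    png,
    purrr,
    ranger,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
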