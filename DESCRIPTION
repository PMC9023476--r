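Package: ocuflow
Title: Conjunctival Microvascular Haemodynamics and Ocular-Biomarker Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Extraction of conjunctival microvascular haemodynamic parameters
    (vessel diameter, axial and cross-sectional velocity, blood flow, wall
    shear rate) from slit-lamp video: sharpest-frame registration, vessel
    segmentation and centerline extraction, Euclidean-distance-transform
    diameter estimation, and spatio-temporal-image velocimetry by
    one-dimension-plus-time continuous wavelet analysis. Fuses the ocular
    parameters with blood biomarker panels under limit-of-detection
    imputation and log transforms, and derives stepwise Wald logistic
    screening scores with full diagnostic-accuracy reporting (Nagelkerke R2,
    Hosmer-Lemeshow, ROC operating characteristics). Includes a
    ground-truthed synthetic video and cohort simulator so every stage is
    verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    EBImage,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
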