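Package: phantomics
Title: Multi-Contrast MRI Radiomics with Synthetic Phantom Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for 3D radiomic characterization of
    breast tumors on multi-contrast MR images (dynamic contrast-enhanced,
    contrast-subtracted, and T2-weighted volumes). Extracts a 342-feature
    radiomic vector per tumor and contrast with six-level gray-value
    quantization averaging, reduces dimension by ReliefF (top 32) or LASSO
    (relaxed penalty retaining over one hundred features), and classifies
    immunohistochemical (ER, PR, HER2) and histological (invasive ductal
    versus lobular carcinoma) status with linear support vector machines or a
    five-layer fully connected network under a patient-wise 5-fold protocol
    with 25 train/validation resamples per fold, reporting AUROC tables.
    Because clinical breast-MRI cohorts are rarely shareable, the package
    includes a seeded synthetic phantom-cohort generator (NIfTI volumes,
    masks, label tables) that emulates the statistical structure the analysis
    assumes, so the full pipeline is testable end to end without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    glmnet,
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    readr,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
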