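Package: radscore
Title: Robust Radiomic Feature Selection and Clinical-Radiomic Scoring for
    CT-Negative Adrenal Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A biomarker-development pipeline for classifying CT-negative
    adrenal glands in primary aldosteronism as lesional (dominant-secretion
    side by adrenal venous sampling) or non-dominant. Implements
    reproducibility (ICC) filtering of radiomic features, an iterative
    stability-selection loop (multi-ratio train/test splits, zero-variance
    and redundancy filters, permutation screening, cross-validated Lasso
    fits, and dual DeLong/permutation acceptance gates), Radiomics Score
    construction under six model families, staged logistic integration of
    screened clinical covariates into a Clinical-Radiomic Score with a
    nomogram export, and evaluation statistics (DeLong AUC inference,
    Youden cutoffs, Hosmer-Lemeshow, calibration, decision-curve analysis).
    Ships a synthetic-data generator with planted signal structure and a
    107-feature extraction front-end for 3D image/mask pairs, so the whole
    pipeline runs end-to-end without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    kernlab,
    MASS,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    RNifti,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
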