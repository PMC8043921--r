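Package: petradiomics
Title: Clinico-Radiomic Modelling of Chemoradiotherapy Response from FDG-PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for predicting pathologic complete response
    to neoadjuvant chemoradiotherapy in esophageal cancer from pre-treatment
    18F-FDG PET. Extracts 101 IBSI-style radiomic features (morphology, local
    intensity, intensity statistics with Moran's I and Geary's C, GLCM, GLRLM,
    GLSZM, NGTDM) from an SUV volume and tumor mask, reduces the feature space
    by Spearman-correlation agglomerative clustering with univariable
    likelihood-ratio screening, builds a suite of twelve logistic prediction
    models combining clinical covariates, LASSO-selected radiomic features and
    the HER2/CD44 immunohistochemistry markers, and internally validates them
    with Harrell's bootstrap optimism correction (Nagelkerke R2, Brier score,
    AUC, discrimination slope, calibration intercept and slope). Includes a
    synthetic-cohort generator (textured PET phantoms, block-correlated
    feature tables, outcomes from a known logistic model) used throughout the
    test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    pheatmap
Config/testthat/edition: 3
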