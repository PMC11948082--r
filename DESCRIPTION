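Package: habitatr
Title: Longitudinal Spatial-Habitat Radiomics for Treatment-Response Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for longitudinal spatial-habitat radiomics of paired
    pre- and mid-treatment 3D MR volumes: intensity preprocessing (bias-field
    correction, isotropic resampling, histogram landmark standardization),
    supervoxel over-segmentation and k-means habitat delineation with
    Calinski-Harabasz cluster-number selection, an IBSI-style texture and
    wavelet feature panel extracted per habitat and whole tumor, a staged
    feature-selection cascade (ICC reliability, variance and Spearman
    redundancy, Mann-Whitney association, LASSO), gradient-boosted response
    prediction with calibration and decision-curve analysis, and downstream
    immune-association scoring (TPM, moderated differential expression,
    preranked and single-sample gene-set enrichment, marker indices, Ro/e).
    Includes a synthetic phantom and cohort generator so every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    cluster,
    glmnet,
    xgboost,
    pROC,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    mclust,
    limma,
    fgsea
Config/testthat/edition: 3
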