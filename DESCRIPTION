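Package: deltarad
Title: Multiphase CT Delta-Radiomics Pipeline for TACE Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a CT-radiomics analysis
    pipeline for predicting transcatheter arterial chemoembolization (TACE)
    response in hepatocellular carcinoma. Extracts 3D volume-of-interest
    first-order, texture-matrix (GLCM, GLRLM, GLZSM) and morphological
    features from four contrast phases, builds inter-phase change-rate
    ("delta") features, selects features by a correlation filter, Welch
    t-test screening and LASSO-penalized logistic regression, classifies
    with a soft-margin kernel support vector machine solved by sequential
    minimal optimization, and evaluates with ROC analysis under hold-out,
    cross-validation and bootstrap schemes. Ships a synthetic multiphase
    tumor-phantom generator so every stage runs end to end without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    utils
Suggests:
    e1071,
    optparse,
    pROC,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
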