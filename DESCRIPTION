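Package: aneucloud
Title: Synthetic Hemodynamic Point Clouds and Integrated Rupture-Status
    Classification of Intracranial Aneurysms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying whether the spatial pattern of wall shear
    stress and inflow-jet impingement on an intracranial aneurysm sac
    carries rupture-status information beyond scalar morphological and
    hemodynamic descriptors.  Provides a seeded synthetic cohort generator
    (parametric sac geometries with pulsatile wall-shear-stress, pressure
    and velocity fields), the ten standard morphological variables, the
    eighteen scalar hemodynamic parameters (TAWSS, OSI, LSA, HOA, energy
    loss and systolic summaries), impingement-zone and inflow-jet
    extraction, a permutation-invariant point-set network that max-pools a
    1,024-dimensional hemodynamic cloud feature, an RFE + kernel-PCA
    feature pipeline, and a repeated stratified cross-validation harness
    comparing five classifiers with and without the cloud feature block.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    class,
    e1071,
    kernlab,
    randomForest,
    xgboost,
    glmnet,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
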