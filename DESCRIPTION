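Package: facesym
Title: Facial and Brain Asymmetry Analysis with Dense Surface Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies facial asymmetry from landmarked 3D face surfaces using
    dense surface models (PCA shape models over densely corresponded meshes and
    their mirror images), signature-based dysmorphism and asymmetry indices
    (SAI), and asymmetry-encoding principal component detection. Computes brain
    asymmetry indices (BASI) from regional neuroimaging measure tables with
    covariate adjustment and z-score quality control, cohort statistics (group
    comparisons, multivariate regression, discrimination testing), and a
    repeated cross-validated LASSO protocol predicting facial asymmetry from
    brain asymmetry with feature selection frequencies. Includes a synthetic
    data generator with planted effects so the whole pipeline is testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    glue,
    generics,
    ggplot2,
    glmnet,
    MASS,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
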