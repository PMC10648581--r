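Package: mirsubtype
Title: Subtype-Specific miRNA Screening and Classification for Endometrial Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for RT-qPCR miRNA panels profiled across tumor
    subtypes. Normalizes quantification-cycle (Ct) values against synthetic
    spike-in controls, screens miRNAs for one-vs-rest differential expression
    with permutation t-test p-values and a fold-change filter, and builds
    multi-miRNA subtype classification models by sequential forward selection
    scored with repeat-averaged stratified cross-validated AUC. Ships a
    synthetic cohort generator that plants known subtype-specific fold changes
    in the Ct domain so the whole pipeline can be validated against ground
    truth, and a published catalogue of subtype-specific fold changes for
    endometrial carcinoma used as the default planted-effect set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
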