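Package: wmconnect
Title: Graph-Theoretical Analysis of White-Matter Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for group-level and single-subject analysis of white-matter
    structural brain networks built from diffusion MRI tractography.  Provides
    sparsity thresholding of weighted connectivity matrices over a grid with
    area-under-curve summarisation, global and nodal graph metrics with
    normalisation against degree-preserving random networks, permutation-based
    group comparison of metric AUCs, the network-based statistic (NBS) for
    connection-level inference with family-wise error control, partial
    correlations with clinical scores, and a nested cross-validated linear
    support vector machine that classifies patients by baseline disease
    progression rate with permutation significance and back-mapping of model
    weights onto individual connections.  A synthetic-cohort generator with
    planted group, subnetwork and progression effects makes the whole pipeline
    testable without patient imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
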