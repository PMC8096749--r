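Package: morphkls
Title: Single-Subject Grey-Matter Morphological Networks via
    Kullback-Leibler Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs single-subject grey-matter morphological brain
    networks from regional voxel-value distributions using kernel density
    estimation and a symmetric Kullback-Leibler divergence mapped to a
    similarity in [0,1] (KLS). Provides sparsity thresholding, small-world
    and efficiency graph metrics with degree-preserving random-network
    references, area-under-curve summaries over a sparsity range,
    permutation-based group inference with FDR correction, a network-based
    statistic (NBS) for localizing altered connections, partial
    correlations with clinical scores, and linear-SVM single-subject
    classification with nested cross-validation and permutation
    significance. Includes a synthetic-cohort generator with planted group
    effects so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    RNifti,
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
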