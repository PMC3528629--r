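Package: simfuse
Title: Multi-View Similarity Fusion for Compound Clustering and Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative integration of multiple compound similarity views
    (bioactivity-profile correlation and structural-fingerprint Tanimoto) into
    a single fused similarity matrix. Convex-combination weights over the
    per-view similarity matrices are learned by alternating a cross-entropy
    nonnegative matrix factorization with an entropy-regularized weight
    optimization on the probability simplex. Includes leave-one-out
    stability-based tuning of the sparseness parameter (average mean
    disagreement and average Dunn's index), hierarchical clustering of the
    fused similarity, compound-target network validation via the average
    within-cluster degree of the common-target projection graph, and fused
    similarity ranking for ligand-based virtual screening. A synthetic-data
    generator with planted cluster structure supports end-to-end testing
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    clue,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
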