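Package: coexpand
Title: Co-Expression-Based Expansion of GWAS Gene Lists and Pathway-Level
    Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates GWAS-derived gene lists with case/control gene
    expression data. Tests whether a gene list shows an unusually
    correlated expression pattern using a random-gene-group permutation
    null, extracts the highly co-expressed sub-cluster and expands it to a
    fixed-size gene list by correlation with the cluster's average
    profile, runs hypergeometric over-representation analysis against GMT
    gene sets with Benjamini-Hochberg correction, assesses cross-dataset
    comparability by correlating per-gene t-statistics, and performs
    pathway-level differential expression on a co-expression network with
    per-gene deviation scores and an exact binomial test for a
    directional tendency. Includes a synthetic-data generator with a
    planted co-expression factor and a planted differentially expressed
    pathway for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
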