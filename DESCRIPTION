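Package: gsla
Title: Gene Set Linkage Analysis with an Inferred Functional Interactome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers strong functional associations between genes by training a
    soft-margin Gaussian-kernel support vector machine on filtered
    experimentally reported protein interactions and multi-evidence feature
    vectors (coexpression, shared annotation, colocalization, domain
    interactions, phylogenetic profiles and interologs), estimates interactome
    size and coverage from prediction sensitivity and specificity, tests
    gene-set-to-gene-set functional association with a two-hypothesis linkage
    statistic (inter-set density plus a degree-preserving permutation null),
    and benchmarks interactome quality by guilt-by-association function
    prediction with precision-recall curves. Ships a synthetic-fixture
    generator with planted module structure so every step runs self-contained.
License: MIT + file LICENSE
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
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
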