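Package: coenrich
Title: Co-Expression Clustering and Gene-Set Enrichment for Drug Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters differentially expressed genes into co-expression groups
    with ten clustering algorithms over seven distance metrics, performs
    hypergeometric gene-set enrichment of each cluster (with Benjamini-Hochberg
    correction and -log2 FDR scoring), matches disease clusters against
    directional drug-perturbation signatures for repositioning, merges
    multi-instance drug hits, and summarises intra-cluster protein-interaction
    connectivity against a degree-preserving null. Includes a seeded synthetic
    data generator so the whole pipeline is testable without external downloads,
    ggplot2 heatmaps for every result type, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    class,
    mclust,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
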