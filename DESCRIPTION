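Package: siggraph
Title: Cross-Cohort Disease Signature Graphs from Multi-Rank NMF
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes case-control transcriptomic cohorts into gene
    signatures with an ensemble of non-negative matrix factorizations run
    at every rank in a range (multi-rank NMF), filters signatures by
    covariate-adjusted association with diagnosis, links signatures across
    cohorts by reciprocal-best-hit Jaccard similarity of their top exposed
    genes with a permutation-tested null, and analyses the resulting
    signature graph: comorbid edge taxonomy, shared-gene categorization,
    hypergeometric over-representation with FDR control, GWAS gene-list
    overlay, and knowledge-graph shortest-path subgraphs. Includes a
    synthetic multi-cohort generator with planted latent factors and known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
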