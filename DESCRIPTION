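Package: comorbinet
Title: Shared-Gene Enrichment Networks for Disorder Comorbidity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative gene-based enrichment analysis for pairs of
    disorder gene lists. Reads and canonicalizes plain-text gene lists,
    intersects them, runs over-representation analysis (hypergeometric
    upper tail with Benjamini-Hochberg adjustment) of the shared genes
    against GMT annotation collections (pathways, molecular functions,
    cellular components, brain regions), assembles significant categories
    and their member genes into one undirected heterogeneous network, and
    ranks nodes by normalized betweenness centrality alongside closeness,
    degree, and component summaries. Ships a seeded simulator of complete
    synthetic studies with planted enriched categories for benchmarking,
    Cytoscape-compatible SIF/GraphML export, and ggplot2 views of the
    centrality and degree distributions.
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
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
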