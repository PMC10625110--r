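Package: emtregulome
Title: Hub-Gene Ranking, Consistency Meta-Integration and Regulome
    Networks for Cancer EMT Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for identifying epithelial-mesenchymal transition
    (EMT) hub genes and kinase-adaptor regulomes from multi-dataset
    transcriptomics and time-lapse kinase-inhibitor screens. Implements
    vote-counting integration of per-dataset differential expression by
    direction consistency, maximal-clique-centrality (MCC) hub ranking on
    merged protein-interaction networks, quantification of cell-scattering
    screens (centroid scatter distance, log fold change, trapezoidal AUC)
    with quantile-based classification of kinase inhibitors into
    adaptor-dependent and adaptor-independent EMT modulators,
    hypergeometric term enrichment with FDR control, Wang semantic
    similarity clustering of enriched terms, and enrichment-map style
    function-connectivity networks. A fully seeded synthetic-data
    generator with planted ground truth makes every stage testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
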