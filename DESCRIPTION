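Package: critnet
Title: Critical Node Identification in Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying candidate biomarker genes
    from two-group expression profiles and a protein-protein interaction
    network. Ranks genes by Welch's t-test, filters differentially expressed
    genes by fold change, extracts the main connected component of the
    interaction graph, computes degree, Brandes betweenness and closeness
    centralities, fits a power law to the degree distribution, selects hub
    nodes (degree above mean + 2 SD), central nodes (top 5% by betweenness and
    closeness) and their intersection as critical nodes, and performs
    hypergeometric gene-set enrichment with Holm correction and kappa-based
    term clustering. Includes generators for synthetic expression matrices,
    preferential-attachment networks and annotation tables, plus readers and
    writers for TSV, SIF and GMT formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
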