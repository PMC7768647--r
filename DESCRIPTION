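Package: phenoRank
Title: Network-Based Ranking of Phenolic Phytochemicals by Influence on
    Cancer Stem Cell Genes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks phenolic phytochemicals by their influence on cancer
    stem cell (CSC) genes. Builds a weighted bipartite phenolic-gene
    interaction graph, weights genes by disease specificity (DSI) and
    disease pleiotropy (DPI) indices derived from gene-disease
    association counts, and iterates a PageRank-inspired multiplicative
    update to a stable phenolic ranking. Also provides a classic
    PageRank power-iteration engine, Lipinski rule-of-five and oral
    bioavailability screening, ADMET threshold classification, and a
    seeded synthetic-data generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'gene_scoring.R'
    'network_build.R'
    'ranking.R'
    'druglikeness.R'
    'synthetic_data.R'
    'pipeline.R'
    'phenoRank-package.R'
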