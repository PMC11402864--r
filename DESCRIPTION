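Package: stressorAOP
Title: Stressor-Centric Adverse Outcome Pathway Networks from
    Toxicogenomic Evidence
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds stressor-centric adverse outcome pathway (AOP) networks
    for chemical risk assessment. Parses AOP-Wiki XML releases into typed
    records, applies a high-confidence AOP filter (non-archived, fully
    specified, weakly connected, with a directed MIE-to-AO path), derives
    chemical-to-key-event associations from five evidence channels
    (high-throughput screening hit calls with cytotoxicity-burst Z-score
    filtering, chemical-gene-phenotype-disease tetramers with GO neighbor
    expansion, two curated endpoint resources, and AOP-Wiki stressor
    records), and assembles a bipartite stressor-AOP network with coverage
    scores and a five-level relevance classification. Includes per-stressor
    AOP projection graphs, directed key-event union networks with
    centrality reports, cumulative weight-of-evidence labels, a seeded
    synthetic-data generator with a ground-truth manifest for end-to-end
    testing, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
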