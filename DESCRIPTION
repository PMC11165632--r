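Package: orepan
Title: Pan-Metagenome Functional Profiling and Biosynthetic Novelty Scoring
    for Ore-Forming-Environment Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for microbiome surveys of mineral-deposit soils.
    Builds counts-per-million normalized taxon-KO functional abundance
    matrices from taxonomy reports and KEGG-orthologue annotation tables,
    classifies orthologues into pan-metagenome core/softcore/shell/cloud
    categories across four datasets with four-set Venn partitioning,
    aggregates orthologues into KEGG pathway modules with twofold screening,
    scores the biosynthetic novelty of isolates from gene-cluster-family
    distances (BiNI), performs desk-scale classical molecular networking of
    tandem mass spectra with the modified cosine score, and computes soil
    geochemistry fold enrichment against crustal reference values. Synthetic
    data generators with planted ground truth make the whole pipeline
    testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
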