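Package: MMInet
Title: Microbiota-Metabolite-Immune Network Construction and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses multipartite networks linking microbiota-derived
    metabolites to immune-system-process gene sets. Parses metabolite records with
    biospecimen and microbial-disposition annotation, merges metabolite-to-gene and
    taxon-to-metabolite association tables, performs hypergeometric
    over-representation analysis with Benjamini-Hochberg control and kappa-based
    term grouping, constructs tripartite microbiota-metabolite-immune networks and
    their projections, clusters entities by Jaccard distance with cophenetic
    linkage validation, derives shared-metabolite commonality graphs with degree,
    strength and articulation-point topology, overlays disease gene sets and
    virus-host interactomes, and quantifies pairwise network rewiring. Includes a
    synthetic-data generator with planted cluster, enrichment and articulation
    structure so every stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    xml2,
    jsonlite,
    vegan,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'MMInet-package.R'
    'associations.R'
    'commonality.R'
    'disease-overlay.R'
    'enrichment.R'
    'hmdb-io.R'
    'layered-network.R'
    'pipeline.R'
    'rewiring.R'
    'show-methods.R'
    'similarity.R'
    'synthetic-universe.R'
    'utils.R'
    'virus-overlay.R'
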