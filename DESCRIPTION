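Package: netpharm
Title: Network Pharmacology Analysis of Multi-Herb Formulas
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for network-pharmacology analysis of a
    multi-herb formula against a disease expression signature: paired
    differential expression with Benjamini-Hochberg false-discovery control,
    oral-bioavailability / drug-likeness screening of herb ingredients,
    intersection of compound targets with disease-specific genes,
    ingredient-target bipartite network construction, two-stage degree- and
    betweenness-centrality core extraction from a protein-protein
    interaction network, and hypergeometric over-representation analysis
    against GO-style and pathway gene sets.  A synthetic-data generator
    emulates every pipeline input (paired expression, compound tables,
    compound-target maps, a scale-free interactome, gene-set collections) so
    the whole analysis is reproducible and testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    fgsea,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
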