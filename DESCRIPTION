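Package: concord
Title: Backbone Concordance, Threshold Meta-Consensus and Motif
    Conservation for Gene-Tree Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether rooted gene trees are concordant
    with a nested species backbone (such as the Gloeobacterales /
    Thermostichales / higher-crown ladder of early cyanobacterial
    evolution), for evaluating alternative root placements, for building
    majority-threshold consensus topologies across single-protein trees
    with unequal taxon sampling, for classifying homologs as
    ortholog-like or paralog-like from pairwise-identity breadth, for
    scoring conservation of short sequence motifs (the GUN4 LxNxLR
    bilin-binding motif in particular) through protein alignments, and
    for designing concatenated supermatrices from protein
    presence/completeness data.  A seeded synthetic-data generator
    produces species trees, gene trees with horizontal transfer and
    duplication events, and motif-constrained sequence alignments so
    that every stage of the pipeline can be exercised against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    Biostrings,
    phytools,
    stats,
    utils,
    yaml
Suggests:
    phangorn,
    jsonlite,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
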