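Package: stressnet
Title: Ranked Knowledge Networks and Intervention Analysis for Plant
    Stress Signaling
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assembling and interrogating ranked molecular
    interaction networks of the kind used in plant stress-signaling
    research. Merges per-resource pairwise interaction tables into a
    condensed knowledge network with a five-level reliability rank,
    models curated signaling as a reaction hypergraph with role-annotated
    participants and a directed signed bipartite projection, generates
    source-to-target shortest-path hypotheses with closest-source
    restriction, plans minimal interventions via rank-capacitated
    max-flow/min-cut with a multi-source super-source construction,
    applies two-contrast proteomics responder filters, and exports
    networks to SIF, DOT, boolnet and tabular formats. Seeded synthetic
    fixture generators with planted ground truth make every analysis
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
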