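Package: godin
Title: Protein Function Prediction by Diffusing GO Terms in a
    Degree-Oriented Interaction Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts protein function from a protein-protein interaction
    (PPI) network and the Gene Ontology (GO). The undirected PPI network is
    oriented by node degree (low-degree "proactive" proteins point at
    high-degree "reactive" hubs), the functional difference across each
    interaction is scored by a coefficient variation of the endpoint
    degrees, and GO terms are diffused iteratively along the oriented
    edges: for every known term an ideal semantic value is computed from
    the edge's descent direction and coefficient variation, and the
    relative of the known term (parent, grandparent, sibling, child or
    grandchild) whose semantic value is closest to the ideal value is
    selected to annotate the partner protein. Includes OBO/GAF readers,
    CAFA-style precision/recall/F evaluation, interaction annotation-group
    analyses, and synthetic generators for ontologies, scale-free-like
    networks and planted annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
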