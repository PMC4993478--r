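Package: cdnp
Title: Cross-Domain Neighborhood Pattern Mining and Predicate Topic
    Discovery for Biomedical Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a heterogeneous schema graph from multiple RDF/OWL
    vocabularies (concepts and predicates labelled by source domain),
    enumerates the five cross-domain neighborhood patterns (Provider,
    Consumer, Reacher, Directional and Non-Directional Connector),
    quantifies predicate associations with probability-based share and
    connectivity scores plus a cross-domain diversity reweighting, and
    clusters predicates into a hierarchy of (possibly overlapping)
    cross-domain topics by bottom-up agglomerative merging with mid-level
    extraction, singleton pooling and connectivity-based refinement.
    Includes predicate/concept/topic rankings, per-topic statistics,
    domain-collaboration graphs with role classification, a seeded
    synthetic multi-domain vocabulary generator with plantable motifs and
    planted topic structure, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
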