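Package: kisaoquery
Title: Query Interface for the Kinetic Simulation Algorithm Ontology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Loads OWL 2 (RDF/XML) releases of the Kinetic Simulation
    Algorithm Ontology (KiSAO) and related KiSAO-shaped ontologies into an
    indexed in-memory graph, and answers taxonomy-level queries (listing,
    identifier and name search, annotations, ancestor/descendant closure)
    and application-level queries (inferred algorithm characteristics and
    parameters, boolean characteristic queries, hybrid-algorithm links, and
    similarity-ranked search for substitute simulation algorithms by
    hierarchy distance). Includes deterministic fixture generators that
    emit KiSAO-shaped OWL files with ground-truth manifests, and a command
    line interface for use in SED-ML tooling pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
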