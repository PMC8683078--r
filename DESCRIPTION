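Package: pathfactoid
Title: Structured Pathway Curation, Entity Grounding and Network Integration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A computational core for author-driven pathway curation. Provides
    a structured pathway-document data model (typed molecular entities,
    complexes, signed mechanism-tagged interactions, free-text context),
    submission-time validation, ranked synonym search that grounds free-text
    labels to gene and chemical database records with organism
    prioritization, top-k retrieval evaluation, export to community standards
    (canonical JSON, SIF, SBGN-ML Process Description, BioPAX Level 3), and
    SIF-network integration queries (merge, bounded-length regulatory paths,
    connectivity deltas contributed by newly curated interactions). A
    fixtures module generates synonym dictionaries, grounding benchmarks,
    pathway documents and schematic networks so everything runs without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    igraph,
    utils,
    stats
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
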