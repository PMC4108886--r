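Package: semevid
Title: Claim-Based Representation of Scientific Evidence as RDF Named Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds, serializes, validates and queries claim-based
    representations of scientific evidence. Scientific claims (assertions),
    their subjects (propositions stored as named RDF graphs), their
    argumentative structure (inference and conjunction links) and their
    provenance (agents, reports, report parts, texts) are first-class
    objects of an RDF dataset following a reasoning-and-discourse
    vocabulary. The package provides constructors for the evidence design
    patterns (subject formalization, reiteration, composition,
    meta-assertion, curator conclusions, alternative interpretation),
    TriG and N-Quads input/output with dataset isomorphism testing,
    materialization of inference closures and derived provenance
    relations, competency-question queries with equivalent SPARQL 1.1
    emission, a programmatic reconstruction of the glutamine-synthetase
    localisation case study and a seeded generator of synthetic evidence
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), igraph, jsonlite, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
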