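Package: goxfer
Title: Gene Ontology Annotation Transfer, Closure and Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for building Gene Ontology (GO) annotation sets for
    poorly annotated genomes by combining curated UniProt-GOA annotations,
    domain-derived annotations from InterProScan output, and annotations
    transferred from well-annotated reference proteomes via reciprocal
    best hits or best hits with identical domain content. Parses go.obo
    ontologies into a typed DAG, applies inter-ontology-link inference and
    ancestor (true-path) closure, reads and writes GAF 2.1 and GeneMerge
    association files, and performs hypergeometric GO term enrichment with
    multiple-testing correction. Includes a generator of fully
    self-consistent synthetic fixture bundles with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
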