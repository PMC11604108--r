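Package: ontomatch
Title: Map Free-Text Descriptions of Biomedical Entities to Ontology Terms
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Maps free-text descriptions of biomedical entities (disease
    names, phenotypes, cell types) to controlled terms in OWL ontologies.
    Candidate mappings are scored either by cosine similarity of TF-IDF
    weighted character n-gram vectors, computed sparsely for whole query
    batches at once, or by classical syntactic similarity metrics
    (Levenshtein, Jaro, Jaro-Winkler, Jaccard, indel). Ontology labels,
    exact and broad synonyms, definitions and the subclass hierarchy are
    extracted from RDF/XML or Turtle serializations; indexes can be cached
    to disk. Generated mappings can be evaluated against human-verified
    benchmark mappings by categorizing each pair through the ontology class
    hierarchy as Same, More Specific, More General, Sibling or Unrelated.
    Includes clients for the BioPortal Annotator and Zooma web annotation
    services, a synthetic-ontology fixture generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    xml2,
    jsonlite,
    httr,
    stringi
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
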