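# Fixture construction shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A hand-built 10-class ontology containing a diamond (A under B and C,
# both under D), a sibling pair, a chain and two isolated terms; written as
# RDF/XML so it also exercises the loader.
makeDiamondOntology <- function(path = tempfile(fileext = ".owl")) {
  iri <- function(x) sprintf("http://purl.obolibrary.org/obo/DMD_%07d", x)
  classes <- list(
    list(n = 1, label = "apex condition", parents = integer()),      # D
    list(n = 2, label = "left branch condition", parents = 1),       # B
    list(n = 3, label = "right branch condition", parents = 1),      # C
    list(n = 4, label = "diamond base condition", parents = c(2, 3)),# A
    list(n = 5, label = "first sibling condition", parents = 2),
    list(n = 6, label = "second sibling condition", parents = 2),
    list(n = 7, label = "chain middle condition", parents = 3),
    list(n = 8, label = "chain leaf condition", parents = 7),
    list(n = 9, label = "isolated condition", parents = integer()),
    list(n = 10, label = "other isolated condition", parents = integer()))
  lines <- c(
    "<?xml version=\"1.0\"?>",
    paste0("<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
           " xmlns:rdfs=\"http://www.w3.org/2000/01/rdf-schema#\"",
           " xmlns:owl=\"http://www.w3.org/2002/07/owl#\">"))
  for (cl in classes) {
    lines <- c(lines, sprintf("  <owl:Class rdf:about=\"%s\">", iri(cl$n)),
               sprintf("    <rdfs:label>%s</rdfs:label>", cl$label),
               vapply(cl$parents, function(p) {
                 sprintf("    <rdfs:subClassOf rdf:resource=\"%s\"/>", iri(p))
               }, character(1)),
               "  </owl:Class>")
  }
  lines <- c(lines, "</rdf:RDF>")
  writeLines(lines, path)
  list(path = path, iri = iri)
}

# Seeded pseudo-random strings (lowercase letters and spaces) for the
# string-metric property tests; includes empty and single-char strings.
randomStringPairs <- function(n, seed) {
  withr::with_seed(seed, {
    alphabet <- c(letters[1:12], " ")
    one <- function() {
      len <- sample(0:12, 1)
      paste(sample(alphabet, len, replace = TRUE), collapse = "")
    }
    data.frame(a = vapply(seq_len(n), function(i) one(), character(1)),
               b = vapply(seq_len(n), function(i) one(), character(1)),
               stringsAsFactors = FALSE)
  })
}

expectMatchesEqual <- function(got, want, tol = 1e-9) {
  expect_equal(nrow(got), nrow(want))
  expect_identical(got$source_index, as.integer(want$source_index))
  expect_identical(got$term_iri, want$term_iri)
  expect_true(all(abs(got$score - want$score) < tol))
}
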