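test_that("loading recovers exactly the generated labels, synonyms and parents", {
  for (seed in c(7, 21)) {
    fx <- generateToyOntology(nTerms = 40, synonymRate = 0.6,
                              broadSynonymRate = 0.3, deprecatedRate = 0.1,
                              seed = seed,
                              path = tempfile(fileext = ".owl"))
    idx <- loadOntology(fx$path, loadConfig(includeBroadSynonyms = TRUE))
    gt <- fx$groundTruth$terms
    expect_setequal(termIRIs(idx), gt$iri)
    for (i in seq_len(nrow(gt))) {
      term <- getTerm(idx, gt$iri[i])
      expect_identical(term$labels, gt$label[i])
      expect_setequal(term$exact_synonyms, gt$exact_synonyms[[i]])
      expect_setequal(term$broad_synonyms, gt$broad_synonyms[[i]])
      expect_setequal(term$parents, gt$parents[[i]] %||% character())
      expect_identical(term$deprecated, gt$deprecated[i])
      expect_true(length(term$labels) + length(term$exact_synonyms) > 0)
    }
  }
})

test_that("labels and exact synonyms land in their respective fields", {
  fx <- diseaseBenchmarkFixture()
  idx <- loadOntology(fx$path)
  mi <- getTerm(idx, "http://www.ebi.ac.uk/efo/EFO_0000612")
  expect_identical(mi$labels, "myocardial infarction")
  expect_identical(mi$exact_synonyms, "heart attack")
  expect_identical(termLabel(idx, mi$iri), "myocardial infarction")
})

test_that("filtering to properties on a class-only ontology is fatal", {
  fx <- generateToyOntology(nTerms = 10, seed = 1)
  expect_error(loadOntology(fx$path, loadConfig("properties")),
               "no terms extracted")
})

test_that("deprecated terms are loaded and flagged but not matchable", {
  fx <- diseaseBenchmarkFixture()
  idx <- loadOntology(fx$path)
  dep_iri <- "http://www.ebi.ac.uk/efo/EFO_0000249"
  expect_true(getTerm(idx, dep_iri)$deprecated)
  expect_false(dep_iri %in% matchableIRIs(idx))
  expect_false(dep_iri %in% buildNameCorpus(idx)$term_iri)
  idx2 <- loadOntology(fx$path, loadConfig(includeDeprecated = TRUE))
  expect_true(dep_iri %in% matchableIRIs(idx2))
})

test_that("ancestors equals a recursive DFS oracle and is monotone", {
  dia <- makeDiamondOntology()
  idx <- loadOntology(dia$path)
  pm <- parentMapFromIndex(idx)
  for (iri in termIRIs(idx)) {
    expect_identical(ancestors(idx, iri), dfsAncestors(pm, iri))
    for (p in parents(idx, iri)) {
      expect_true(all(ancestors(idx, p) %in% ancestors(idx, iri)))
    }
  }
  # the diamond: base has both branches and the apex, deduplicated
  expect_identical(ancestors(idx, dia$iri(4)),
                   sort(c(dia$iri(1), dia$iri(2), dia$iri(3))))
  expect_identical(ancestors(idx, dia$iri(1)), character())
  # chain A < B < C
  expect_identical(ancestors(idx, dia$iri(8)),
                   sort(c(dia$iri(1), dia$iri(3), dia$iri(7))))
  # larger generated fixtures against the same oracle
  for (seed in c(3, 11)) {
    fx <- generateToyOntology(nTerms = 60, diamondRate = 0.3, seed = seed,
                              path = tempfile(fileext = ".owl"))
    gidx <- loadOntology(fx$path)
    gpm <- parentMapFromIndex(gidx)
    for (iri in termIRIs(gidx)) {
      expect_identical(ancestors(gidx, iri), dfsAncestors(gpm, iri))
    }
  }
  expect_error(ancestors(idx, "http://example.org/nope"), "unknown term IRI")
})

test_that("ancestor computation terminates on subclass cycles", {
  path <- tempfile(fileext = ".owl")
  writeLines(c(
    "<?xml version=\"1.0\"?>",
    paste0("<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
           " xmlns:rdfs=\"http://www.w3.org/2000/01/rdf-schema#\"",
           " xmlns:owl=\"http://www.w3.org/2002/07/owl#\">"),
    "  <owl:Class rdf:about=\"http://x.org/A\">",
    "    <rdfs:label>a</rdfs:label>",
    "    <rdfs:subClassOf rdf:resource=\"http://x.org/B\"/>",
    "  </owl:Class>",
    "  <owl:Class rdf:about=\"http://x.org/B\">",
    "    <rdfs:label>b</rdfs:label>",
    "    <rdfs:subClassOf rdf:resource=\"http://x.org/A\"/>",
    "  </owl:Class>",
    "</rdf:RDF>"), path)
  idx <- loadOntology(path)
  expect_setequal(ancestors(idx, "http://x.org/A"),
                  c("http://x.org/A", "http://x.org/B"))
})

test_that("Turtle and RDF/XML serializations load equivalently", {
  ttl <- system.file("extdata", "mini.ttl", package = "ontomatch")
  idx <- loadOntology(ttl, loadConfig(includeDeprecated = TRUE))
  expect_equal(nTerms(idx), 3L)
  t1 <- getTerm(idx, "http://purl.obolibrary.org/obo/EX_0000001")
  expect_identical(t1$labels, "cardiac arrest")
  expect_identical(t1$exact_synonyms, "heart arrest")
  expect_identical(t1$definitions, "cessation of the heartbeat")
  t2 <- getTerm(idx, "http://purl.obolibrary.org/obo/EX_0000002")
  expect_identical(t2$parents, t1$iri)
  t3 <- getTerm(idx, "http://purl.obolibrary.org/obo/EX_0000003")
  expect_true(t3$deprecated)
  # the anonymous restriction parent was skipped, not linked
  expect_identical(t3$parents, character())
  expect_gte(idx@stats[["anonymous_parents_skipped"]], 1L)
})

test_that("fallback naming derives a matchable name from the IRI", {
  path <- tempfile(fileext = ".owl")
  writeLines(c(
    "<?xml version=\"1.0\"?>",
    paste0("<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
           " xmlns:owl=\"http://www.w3.org/2002/07/owl#\">"),
    "  <owl:Class rdf:about=\"http://x.org/MyocardialInfarction_acute\"/>",
    "</rdf:RDF>"), path)
  idx <- loadOntology(path)
  expect_identical(getTerm(idx, termIRIs(idx))$labels,
                   "Myocardial Infarction acute")
})

test_that("unreadable and unparseable sources fail fatally", {
  expect_error(loadOntology(tempfile()), "cannot read")
  bad <- tempfile(fileext = ".owl")
  writeLines("<?xml version=\"1.0\"?><broken", bad)
  expect_error(loadOntology(bad), "parse")
})

test_that("cache save/load round-trips the observable term data", {
  fx <- generateToyOntology(nTerms = 30, synonymRate = 0.5,
                            broadSynonymRate = 0.4, deprecatedRate = 0.1,
                            seed = 13, path = tempfile(fileext = ".owl"))
  cfg <- loadConfig(includeBroadSynonyms = TRUE)
  idx <- loadOntology(fx$path, cfg)
  dir <- file.path(tempdir(), "cache-roundtrip")
  saveOntologyCache(idx, dir)
  idx2 <- loadOntologyCache(dir)
  expect_identical(termIRIs(idx2), termIRIs(idx))
  for (iri in termIRIs(idx)) {
    expect_identical(getTerm(idx2, iri), getTerm(idx, iri))
  }
  expect_identical(idx2@loadConfig@includeBroadSynonyms, TRUE)
  expect_identical(idx2@source, idx@source)
  for (iri in termIRIs(idx)) {
    expect_identical(ancestors(idx2, iri), ancestors(idx, iri))
  }
  # broad synonyms survive the round trip into the corpus
  expect_true("broad_synonym" %in% buildNameCorpus(idx2)$name_kind)
})

test_that("cache loading rejects missing or incompatible caches", {
  expect_error(loadOntologyCache(tempfile()), "missing cache")
  fx <- generateToyOntology(nTerms = 5, seed = 2)
  dir <- file.path(tempdir(), "cache-badversion")
  saveOntologyCache(loadOntology(fx$path), dir)
  meta <- jsonlite::fromJSON(file.path(dir, "metadata.json"),
                             simplifyVector = TRUE)
  meta$cache_major_version <- meta$cache_major_version + 99L
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE)
  expect_error(loadOntologyCache(dir), "re-cache")
})
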