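test_that("an exact label match scores 1 at rank 1", {
  fx <- generateToyOntology(nTerms = 30, seed = 7,
                            path = tempfile(fileext = ".owl"))
  idx <- loadOntology(fx$path)
  corpus <- buildNameCorpus(idx)
  q <- fixtureQueries(fx)
  got <- tfidfMap(q$query, corpus)
  top <- got[!duplicated(got$source_index), ]
  expect_identical(top$term_iri, q$true_iri)
  expect_true(all(abs(top$score - 1) < 1e-9))
})

test_that("queries match through exact synonyms", {
  fx <- diseaseBenchmarkFixture()
  idx <- loadOntology(fx$path)
  got <- tfidfMap("heart attack", buildNameCorpus(idx))
  expect_identical(got$term_iri[1], "http://www.ebi.ac.uk/efo/EFO_0000612")
  expect_equal(got$score[1], 1, tolerance = 1e-12)
  expect_identical(got$name_kind[1], "exact_synonym")
})

test_that("sparse batch scores equal the dense brute-force computation", {
  # a 5-name toy corpus checked end to end
  corpus <- data.frame(
    term_iri = paste0("http://x.org/T", 1:5),
    name = c("heart failure", "heart attack", "cardiac arrest",
             "kidney failure", "renal failure"),
    name_kind = "label", stringsAsFactors = FALSE)
  cfg <- mapperConfig("tfidf", minScore = 0, maxMappings = 5)
  got <- tfidfMap("heart failure", corpus, cfg)
  want <- denseTfidfOracle("heart failure", corpus, minScore = 0,
                           maxMappings = 5)
  expectMatchesEqual(got, want)
  expect_equal(got$score[1], 1, tolerance = 1e-12)
  # and across seeded fixtures with corrupted queries
  for (seed in c(2, 8)) {
    fx <- generateToyOntology(nTerms = 40, synonymRate = 0.5, seed = seed,
                              path = tempfile(fileext = ".owl"))
    idx <- loadOntology(fx$path)
    corpus <- buildNameCorpus(idx)
    queries <- fixtureQueries(fx, nEdits = 1, seed = seed + 100)$query[1:15]
    got <- tfidfMap(queries, corpus)
    want <- denseTfidfOracle(queries, corpus)
    expectMatchesEqual(got, want)
  }
})

test_that("corpus-only IDF fitting is supported and matches its oracle", {
  corpus <- data.frame(
    term_iri = paste0("http://x.org/T", 1:3),
    name = c("asthma", "chronic asthma", "allergic asthma"),
    name_kind = "label", stringsAsFactors = FALSE)
  cfg <- mapperConfig("tfidf", minScore = 0, maxMappings = 3,
                      fitCorpusOnly = TRUE)
  got <- tfidfMap("asthma", corpus, cfg)
  want <- denseTfidfOracle("asthma", corpus, minScore = 0, maxMappings = 3,
                           fitCorpusOnly = TRUE)
  expectMatchesEqual(got, want)
})

test_that("too-short queries yield no matches rather than an error", {
  corpus <- data.frame(term_iri = "http://x.org/T1", name = "asthma",
                       name_kind = "label", stringsAsFactors = FALSE)
  got <- tfidfMap(data.frame(text = "q"), corpus,
                  mapperConfig("tfidf", ngramSize = 5))
  expect_equal(nrow(got), 0)
})

test_that("results are deterministic and truncation is monotone", {
  fx <- generateToyOntology(nTerms = 50, seed = 31,
                            path = tempfile(fileext = ".owl"))
  corpus <- buildNameCorpus(loadOntology(fx$path))
  queries <- fixtureQueries(fx, nEdits = 2, seed = 5)$query[1:10]
  r1 <- tfidfMap(queries, corpus, mapperConfig(minScore = 0.1))
  r2 <- tfidfMap(queries, corpus, mapperConfig(minScore = 0.1))
  expect_identical(r1, r2)
  for (k in 1:3) {
    rk <- tfidfMap(queries, corpus,
                   mapperConfig(maxMappings = k, minScore = 0.1))
    rk1 <- tfidfMap(queries, corpus,
                    mapperConfig(maxMappings = k + 1, minScore = 0.1))
    for (s in unique(rk$source_index)) {
      a <- rk[rk$source_index == s, ]
      b <- rk1[rk1$source_index == s, ]
      expect_identical(a$term_iri, b$term_iri[seq_len(nrow(a))])
    }
  }
  expect_true(all(r1$score >= 0.1 & r1$score <= 1))
})

test_that("duplicate names collapse to one corpus entry per term", {
  path <- tempfile(fileext = ".owl")
  writeLines(c(
    "<?xml version=\"1.0\"?>",
    paste0("<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
           " xmlns:rdfs=\"http://www.w3.org/2000/01/rdf-schema#\"",
           " xmlns:owl=\"http://www.w3.org/2002/07/owl#\"",
           " xmlns:oboInOwl=\"http://www.geneontology.org/formats/oboInOwl#\">"),
    "  <owl:Class rdf:about=\"http://x.org/A\">",
    "    <rdfs:label>Asthma</rdfs:label>",
    "    <oboInOwl:hasExactSynonym>asthma</oboInOwl:hasExactSynonym>",
    "    <oboInOwl:hasExactSynonym>bronchial asthma</oboInOwl:hasExactSynonym>",
    "    <oboInOwl:hasBroadSynonym>lung disease</oboInOwl:hasBroadSynonym>",
    "  </owl:Class>",
    "</rdf:RDF>"), path)
  idx <- loadOntology(path)
  corpus <- buildNameCorpus(idx, includeBroad = FALSE)
  expect_equal(nrow(corpus), 2)            # label+synonym dedup, no broad
  expect_identical(corpus$name_kind[corpus$name == "asthma"], "label")
  corpus_b <- buildNameCorpus(idx, includeBroad = TRUE)
  expect_equal(nrow(corpus_b), 3)
})
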