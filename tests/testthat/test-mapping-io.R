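test_that("line-mode source files skip blank lines and keep order", {
  f <- tempfile()
  writeLines(c("asthma", "", " heart attack "), f)
  st <- readSourceTerms(f)
  expect_identical(st$text, c("asthma", "heart attack"))
})

test_that("table-mode source files honour delimiter, column and ids", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("term,code", "asthma,T1", "flu,T2"), f)
  st <- readSourceTerms(f, delimiter = ",", column = "term",
                        idColumn = "code")
  expect_identical(st$text, c("asthma", "flu"))
  expect_identical(st$source_id, c("T1", "T2"))
  expect_error(readSourceTerms(f, delimiter = ",", column = "nope"),
               "available columns: term, code")
  g <- tempfile(fileext = ".tsv")
  writeLines(c("name\tgroup", paste0("t", 1:4, "\tg")), g)
  expect_identical(readSourceTerms(g, delimiter = "\t")$text,
                   paste0("t", 1:4))
  h <- tempfile(); file.create(h)
  expect_error(readSourceTerms(h), "no source terms")
})

test_that("end-to-end mapping refinds every fixture label", {
  fx <- generateToyOntology(nTerms = 50, deprecatedRate = 0, seed = 11,
                            path = tempfile(fileext = ".owl"))
  q <- fixtureQueries(fx)
  tab <- mapTerms(q$query, fx$path)
  rows <- mappingRows(tab)
  top <- rows[!duplicated(rows$source_term), ]
  expect_equal(nrow(top), 50)
  expect_identical(top$term_iri, q$true_iri)
  expect_true(all(abs(top$score - 1) < 1e-9))
  expect_equal(nrow(unmappedTerms(tab)), 0)
  # input order preserved, scores non-increasing within each source
  expect_identical(unique(rows$source_term), q$query)
  for (s in unique(rows$source_term)) {
    sc <- rows$score[rows$source_term == s]
    expect_true(all(diff(sc) <= 1e-12))
  }
})

test_that("hopeless queries are listed as unmapped, not errors", {
  fx <- generateToyOntology(nTerms = 20, seed = 3,
                            path = tempfile(fileext = ".owl"))
  tab <- mapTerms(c(fixtureQueries(fx)$query[1], "zzqx"), fx$path)
  expect_identical(unmappedTerms(tab)$source_term, "zzqx")
  tab2 <- mapTerms(c(fixtureQueries(fx)$query[1], "zzqx"), fx$path,
                   includeUnmapped = FALSE)
  expect_equal(nrow(unmappedTerms(tab2)), 0)
  expect_identical(mappingRows(tab2), mappingRows(tab))
})

test_that("a multi-word phrase maps to the dominant ontology term", {
  fx <- diseaseBenchmarkFixture()
  idx <- loadOntology(fx$path)
  tab <- mapTerms("Hayfever or allergic rhinitis", idx)
  expect_identical(mappingRows(tab)$term_label[1], "allergic rhinitis")
})

test_that("mapping tables round-trip through disk", {
  fx <- generateToyOntology(nTerms = 20, seed = 19,
                            path = tempfile(fileext = ".owl"))
  q <- fixtureQueries(fx)$query[1:5]
  tab <- mapTerms(c(q, "zzqx"), fx$path)
  out <- tempfile(fileext = ".csv")
  writeMappingTable(tab, out)
  txt <- readLines(out)
  expect_true(any(grepl("^# mapper: tfidf", txt)))
  expect_true(any(grepl("1\\.000000", txt)))
  n_data <- length(txt) - sum(grepl("^#", txt)) - 1L
  expect_equal(n_data, nrow(mappingRows(tab)) + 1L)  # + the unmapped row
  back <- readMappingTable(out)
  expect_identical(mappingRows(back)$source_term,
                   mappingRows(tab)$source_term)
  expect_identical(mappingRows(back)$term_iri, mappingRows(tab)$term_iri)
  expect_equal(mappingRows(back)$score, mappingRows(tab)$score,
               tolerance = 1e-6)
  expect_identical(unmappedTerms(back)$source_term, "zzqx")
  expect_identical(back@metadata$mapper, "tfidf")
  # tsv round trip too
  out2 <- tempfile(fileext = ".tsv")
  writeMappingTable(tab, out2, format = "tsv")
  back2 <- readMappingTable(out2)
  expect_identical(mappingRows(back2)$term_iri, mappingRows(tab)$term_iri)
})

test_that("SSSOM-style tables are read with mapper external", {
  f <- tempfile(fileext = ".sssom.tsv")
  writeLines(c(
    "subject_id\tsubject_label\tpredicate_id\tobject_id",
    "A:1\talpha syndrome\tskos:exactMatch\thttp://purl.obolibrary.org/obo/X_1",
    "A:2\tbeta syndrome\tskos:exactMatch\thttp://purl.obolibrary.org/obo/X_2",
    "A:3\tgamma syndrome\tskos:exactMatch\thttp://purl.obolibrary.org/obo/X_3"),
    f)
  tab <- readMappingTable(f)
  rows <- mappingRows(tab)
  expect_equal(nrow(rows), 3)
  expect_identical(unique(rows$mapper), "external")
  expect_identical(rows$source_term,
                   paste(c("alpha", "beta", "gamma"), "syndrome"))
  expect_identical(rows$term_curie[1], "X:1")
})

test_that("degenerate tables are handled explicitly", {
  f <- tempfile(fileext = ".tsv")
  writeLines("subject_id\tobject_id", f)
  expect_warning(tab <- readMappingTable(f), "no data rows")
  expect_equal(nrow(mappingRows(tab)), 0)
  g <- tempfile(fileext = ".csv")
  writeLines(c("foo,bar", "1,2"), g)
  expect_error(readMappingTable(g), "detected columns: foo, bar")
})

test_that("repeat runs produce byte-identical output files", {
  fx <- generateToyOntology(nTerms = 25, seed = 29,
                            path = tempfile(fileext = ".owl"))
  q <- c(fixtureQueries(fx, nEdits = 1, seed = 2)$query, "zzqx")
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeMappingTable(mapTerms(q, fx$path, timestamp = FALSE), f1)
  writeMappingTable(mapTerms(q, fx$path, timestamp = FALSE), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
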