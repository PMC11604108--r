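# Synthetic ontology fixtures: small OWL documents with known ground truth,
# so the loader, mappers and categorizer are testable offline.

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x
}

.SYLLABLES <- c("ab", "bri", "cor", "cul", "dex", "dor", "eph", "fen",
                "gal", "gri", "hep", "hax", "jun", "kel", "lim", "mol",
                "mur", "nex", "nir", "os", "pol", "pra", "quel", "rin",
                "rud", "sev", "sol", "tam", "til", "ul", "vor", "vos",
                "wex", "yol", "zan")
.DISEASE_TOKENS <- c("syndrome", "disease", "disorder", "deficiency",
                     "carcinoma", "fibrosis", "dystrophy", "atrophy",
                     "sclerosis", "stenosis", "neuropathy", "dermatitis",
                     "anemia", "edema", "lesion")

# Multi-word pseudo-biomedical names: syllable concatenations plus real
# disease-like tokens, so character n-gram statistics are non-degenerate
# (uniform random strings would make cosine scores unrealistically flat).
pseudoWord <- function() {
  paste(sample(.SYLLABLES, sample(2:3, 1), replace = TRUE), collapse = "")
}

pseudoName <- function() {
  first <- pseudoWord()
  second <- if (stats::runif(1) < 0.6) sample(.DISEASE_TOKENS, 1)
            else pseudoWord()
  paste(first, second)
}

#' Generate a synthetic toy ontology with ground truth
#'
#' Emits a rooted hierarchy of named classes serialized as RDF/XML, with an
#' `rdfs:label` on every class, exact synonyms at `synonymRate`, broad
#' synonyms at `broadSynonymRate`, deprecation flags at `deprecatedRate`,
#' and a second parent at `diamondRate` (producing DAG diamonds that
#' exercise the closure and sibling logic). Identical arguments produce a
#' byte-identical document.
#'
#' @param nTerms number of classes (>= 2).
#' @param maxChildren maximum direct children per class.
#' @param synonymRate probability that a class has 1-2 exact synonyms.
#' @param broadSynonymRate probability of one broad synonym.
#' @param deprecatedRate probability that a non-root class is deprecated.
#' @param diamondRate probability of a second parent.
#' @param seed RNG seed; the generator never perturbs the caller's RNG
#'   state.
#' @param path output file (default: a file in `tempdir()` named from the
#'   arguments).
#' @return list with `path` (the OWL file) and `groundTruth`, itself a list
#'   whose `terms` data.frame records per term the IRI, label, synonyms
#'   (list columns), parents (list column) and deprecation flag.
#' @examples
#' fx <- generateToyOntology(nTerms = 12, seed = 7)
#' fx$groundTruth$terms$label
#' @export
generateToyOntology <- function(nTerms = 50L, maxChildren = 5L,
                                synonymRate = 0.4, broadSynonymRate = 0.1,
                                deprecatedRate = 0.05, diamondRate = 0.15,
                                seed = 1L, path = NULL) {
  nTerms <- as.integer(nTerms)
  if (nTerms < 2L) omStop("nTerms must be >= 2")
  if (maxChildren < 1L) omStop("maxChildren must be >= 1")
  if (is.null(path)) {
    path <- file.path(tempdir(),
                      sprintf("toy_n%d_seed%d.owl", nTerms, as.integer(seed)))
  }
  withLocalSeed(seed, {
    labels <- character(nTerms)
    used <- character()
    for (i in seq_len(nTerms)) {
      repeat {
        cand <- pseudoName()
        if (!cand %in% used) break
      }
      labels[i] <- cand
      used <- c(used, cand)
    }
    iris <- sprintf("http://purl.obolibrary.org/obo/TOY_%07d", seq_len(nTerms))
    parents <- vector("list", nTerms)
    n_children <- integer(nTerms)
    for (i in seq(2L, nTerms)) {
      eligible <- which(n_children[seq_len(i - 1L)] < maxChildren)
      p1 <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
      par <- p1
      if (stats::runif(1) < diamondRate && length(eligible) > 1L) {
        others <- setdiff(eligible, p1)
        p2 <- if (length(others) == 1L) others else sample(others, 1L)
        par <- c(par, p2)
      }
      parents[[i]] <- iris[par]
      n_children[par] <- n_children[par] + 1L
    }
    exact_syn <- vector("list", nTerms)
    broad_syn <- vector("list", nTerms)
    for (i in seq_len(nTerms)) {
      if (stats::runif(1) < synonymRate) {
        k <- sample(1:2, 1L)
        syn <- character(k)
        for (s in seq_len(k)) {
          repeat {
            cand <- pseudoName()
            if (!cand %in% used) break
          }
          syn[s] <- cand
          used <- c(used, cand)
        }
        exact_syn[[i]] <- syn
      } else exact_syn[[i]] <- character()
      if (stats::runif(1) < broadSynonymRate) {
        repeat {
          cand <- pseudoName()
          if (!cand %in% used) break
        }
        broad_syn[[i]] <- cand
        used <- c(used, cand)
      } else broad_syn[[i]] <- character()
    }
    deprecated <- c(FALSE,
                    stats::runif(nTerms - 1L) < deprecatedRate)
    has_def <- stats::runif(nTerms) < 0.3

    lines <- c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      paste0("<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
             " xmlns:rdfs=\"http://www.w3.org/2000/01/rdf-schema#\""),
      paste0("         xmlns:owl=\"http://www.w3.org/2002/07/owl#\"",
             " xmlns:oboInOwl=\"http://www.geneontology.org/formats/oboInOwl#\""),
      "         xmlns:skos=\"http://www.w3.org/2004/02/skos/core#\">",
      "  <owl:Ontology rdf:about=\"http://purl.obolibrary.org/obo/toy.owl\">",
      sprintf("    <owl:versionInfo>seed-%d</owl:versionInfo>",
              as.integer(seed)),
      "  </owl:Ontology>")
    for (i in seq_len(nTerms)) {
      lines <- c(lines, sprintf("  <owl:Class rdf:about=\"%s\">", iris[i]))
      lines <- c(lines, sprintf("    <rdfs:label>%s</rdfs:label>",
                                xmlEscape(labels[i])))
      for (s in exact_syn[[i]]) {
        lines <- c(lines,
          sprintf("    <oboInOwl:hasExactSynonym>%s</oboInOwl:hasExactSynonym>",
                  xmlEscape(s)))
      }
      for (s in broad_syn[[i]]) {
        lines <- c(lines,
          sprintf("    <oboInOwl:hasBroadSynonym>%s</oboInOwl:hasBroadSynonym>",
                  xmlEscape(s)))
      }
      for (p in parents[[i]]) {
        lines <- c(lines,
                   sprintf("    <rdfs:subClassOf rdf:resource=\"%s\"/>", p))
      }
      if (deprecated[i]) {
        lines <- c(lines, "    <owl:deprecated>true</owl:deprecated>")
      }
      if (has_def[i]) {
        lines <- c(lines,
          sprintf("    <skos:definition>a synthetic condition involving %s</skos:definition>",
                  xmlEscape(labels[i])))
      }
      lines <- c(lines, "  </owl:Class>")
    }
    lines <- c(lines, "</rdf:RDF>")
    writeLines(lines, path, useBytes = TRUE)

    gt <- list(terms = data.frame(
      iri = iris, label = labels,
      exact_synonyms = I(exact_syn), broad_synonyms = I(broad_syn),
      parents = I(parents), deprecated = deprecated,
      stringsAsFactors = FALSE))
    list(path = path, groundTruth = gt)
  })
}

#' Apply seeded random character edits to a label
#'
#' Applies `nEdits` single-character substitutions, insertions or deletions
#' at seeded positions; `nEdits = 0` returns the label unchanged. Used to
#' build typo-corrupted query sets with a known true term.
#'
#' @param label input string; must be longer than `nEdits`.
#' @param nEdits number of edits (>= 0).
#' @param seed RNG seed.
#' @return the corrupted string; its Levenshtein distance to `label` is at
#'   most `nEdits`.
#' @examples
#' corruptLabel("melancholia", 1, seed = 5)
#' corruptLabel("melancholia", 0, seed = 1)
#' @export
corruptLabel <- function(label, nEdits, seed) {
  if (nEdits < 0L) omStop("nEdits must be >= 0")
  if (nchar(label) <= nEdits) omStop("label too short for ", nEdits, " edits")
  if (nEdits == 0L) return(label)
  alphabet <- c(letters, " ")
  withLocalSeed(seed, {
    chars <- strsplit(label, "", fixed = TRUE)[[1]]
    for (e in seq_len(nEdits)) {
      op <- sample(c("sub", "ins", "del"), 1L)
      pos <- sample(length(chars), 1L)
      if (op == "sub") {
        repl <- sample(setdiff(alphabet, chars[pos]), 1L)
        chars[pos] <- repl
      } else if (op == "ins") {
        chars <- append(chars, sample(alphabet, 1L), after = pos)
      } else if (length(chars) > 1L) {
        chars <- chars[-pos]
      }
    }
    paste(chars, collapse = "")
  })
}

#' Build a corrupted query set from fixture ground truth
#'
#' One query per non-deprecated fixture term: its label with `nEdits`
#' seeded character edits applied.
#'
#' @param fixture result of [generateToyOntology()].
#' @param nEdits edits per query (default 0 = the labels themselves).
#' @param seed RNG seed stream for the per-query corruption.
#' @return `data.frame` with columns `query`, `true_iri`, `n_edits`.
#' @export
fixtureQueries <- function(fixture, nEdits = 0L, seed = 1L) {
  terms <- fixture$groundTruth$terms
  terms <- terms[!terms$deprecated, , drop = FALSE]
  queries <- terms$label
  if (nEdits > 0L) {
    queries <- vapply(seq_along(queries), function(i) {
      corruptLabel(queries[i], nEdits, seed = seed + i)
    }, character(1))
  }
  data.frame(query = queries, true_iri = terms$iri,
             n_edits = as.integer(nEdits), stringsAsFactors = FALSE)
}

#' Curated disease-hierarchy benchmark fixture
#'
#' A small hand-written disease ontology whose hierarchy reproduces
#' characteristic tool-versus-benchmark situations seen when mapping
#' phenotype descriptions to a large disease ontology: a term mapped one
#' level above the expected one (allergic rhinitis vs seasonal allergic
#' rhinitis), one level below (uremia vs kidney failure), two siblings
#' under one parent (chronic bronchitis vs emphysema), a deprecated
#' duplicate term (the two Alzheimer entries), and a label/synonym pair
#' (myocardial infarction, exact synonym "heart attack"). Ships with the
#' expected category for each encoded pair.
#'
#' @return list with `path` (the OWL file shipped with the package) and
#'   `expected`, a data.frame with columns `input_text`, `tool_iri`,
#'   `benchmark_iri`, `category`.
#' @examples
#' fx <- diseaseBenchmarkFixture()
#' idx <- loadOntology(fx$path)
#' categorizePair(idx, fx$expected$tool_iri[1], fx$expected$benchmark_iri[1])
#' @export
diseaseBenchmarkFixture <- function() {
  path <- system.file("extdata", "disease_benchmark.owl",
                      package = "ontomatch", mustWork = TRUE)
  efo <- function(x) paste0("http://www.ebi.ac.uk/efo/EFO_", x)
  obo <- function(x) paste0("http://purl.obolibrary.org/obo/", x)
  expected <- data.frame(
    input_text = c("Hayfever or allergic rhinitis", "Uremia",
                   "Emphysema/chronic bronchitis", "Alzheimer's disease",
                   "General pain for 3+ months", "heart attack"),
    tool_iri = c(efo("0005854"), efo("1001226"), efo("0006505"),
                 obo("MONDO_0004975"), efo("0003843"), efo("0000612")),
    benchmark_iri = c(efo("0003956"), efo("1002048"), efo("0000464"),
                      efo("0000249"), obo("HP_0012532"), efo("0000612")),
    category = c("MoreGeneral", "MoreSpecific", "Sibling", "Unrelated",
                 "MoreGeneral", "Same"),
    stringsAsFactors = FALSE)
  list(path = path, expected = expected)
}
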