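---
title: "Mapping free text to ontology terms: methods and design notes"
author: "ontomatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping free text to ontology terms: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontomatch)
```

## The problem

Free-text descriptions of biomedical entities — "cardiac failure", "heart
failure", "hayfever or allergic rhinitis" — need to be grounded to
controlled terms in an ontology before datasets can be searched or
integrated. `ontomatch` generates scored candidate mappings from input
strings ("source terms") to terms of a target OWL ontology, and provides
the evaluation machinery to compare generated mappings against
human-verified ones through the ontology's class hierarchy.

## What is extracted from an ontology

For each term the loader collects:

* labels — `rdfs:label`, `skos:prefLabel`;
* exact synonyms — `oboInOwl:hasExactSynonym`, plus the ontology-specific
  properties `NCIT:P90` and `EFO:alternative_term`;
* broad synonyms — `oboInOwl:hasBroadSynonym` (indexed only on request,
  since a broad synonym names a *more general* concept and dilutes
  precision);
* definitions — `skos:definition`, `IAO:0000115`;
* the asserted hierarchy — direct parents, children and instances via
  `rdfs:subClassOf` / `rdfs:subPropertyOf` / `rdf:type`;
* deprecation — `owl:deprecated = true` or subclassing of
  `oboInOwl:ObsoleteClass`.

Extra annotation-property IRIs can be supplied in `loadConfig()`. Both
RDF/XML and Turtle serializations are read, from a file path or an http(s)
URL, and a loaded index can be cached to disk as JSON and reloaded
losslessly (the cache refuses to load across major versions of the
package).

Assumptions and conventions worth stating explicitly:

* **Entailment is structural.** "T is a subclass of H" is decided on the
  reflexive-free transitive closure of *asserted* parent edges, memoized
  per index and computed as a fixpoint so subclass cycles terminate (a
  term on a cycle is its own ancestor). A reasoner can be plugged in as a
  pre-step via `options(ontomatch.reasoner = ...)` to add inferred edges;
  by default no reasoning is performed, which keeps loading deterministic
  and dependency-free.
* **Anonymous classes** (e.g. `owl:Restriction`) in parent position are
  skipped and counted, never linked; hierarchy references leaving the
  extracted term set are dropped with a warning count.
* **Deprecated terms are loaded but not matchable.** They stay in the
  index so a benchmark entry pointing at an obsolete term can still be
  categorized, but they are excluded from the name corpus unless
  `includeDeprecated = TRUE`. This is what lets the mapper "avoid" an
  obsolete duplicate and map to its non-deprecated replacement.
* **Naming fallback.** A term with no label and no synonym gets a name
  derived from its IRI fragment (underscores and camelCase boundaries
  become spaces), so every term is matchable.
* **Imports.** The document is processed as delivered by the parser; no
  imports resolution is attempted. If a merged imports closure is wanted,
  merge it upstream (e.g. with ROBOT) before loading.
* **Compact identifiers.** OBO PURLs and EFO IRIs yield CURIEs
  (`MONDO:0004975`, `EFO:0000249`); other IRIs are shown in full.

## The TF-IDF mapper

Each normalized string (lowercase, Unicode NFC, collapsed whitespace) is
padded with one leading and one trailing space and decomposed into
character n-grams of length `ngramSize` (default 3). Padding makes word
boundaries part of the token stream and guarantees at least one trigram
for any non-empty string. **No tokens are removed**: stop-word removal is
deliberately absent because it makes "non-hodgkin's lymphoma" degrade to
"hodgkin's lymphoma" — exactly the negation failure a mapper must not
introduce.

Weights use the smooth IDF `log((1 + N)/(1 + df)) + 1` with raw term
counts, followed by l2 normalization, so the score of a pair is a cosine
in [0, 1] and an exact (normalized) string match scores 1. Scoring a
query batch is a single sparse matrix product (`Matrix`), which is what
makes tens of thousands of queries practical; the per-query top-*n*
selection then collapses scores to the best name per term, ranks by
descending score with ties broken by term IRI (reproducibility), filters
at `minScore` and truncates to `maxMappings`.

Numerical conventions: a similarity of exactly 0 (no shared n-grams) is
never reported as a match, even at `minScore = 0`; a query shorter than
the n-gram window yields no matches and surfaces as *unmapped*, not as an
error.

Two genuinely open choices were fixed as follows:

* **Character rather than word n-grams.** Character trigrams are robust
  to typos, inflection and word order, and behave sensibly for short
  clinical phrases where word-level vectors are nearly orthogonal.
* **IDF fitting corpus.** By default IDF is fitted on the union of the
  ontology names and the query batch, so both sides share one
  vocabulary; the documented caveat is that scores can shift slightly
  between query batches. `fitCorpusOnly = TRUE` fits on the ontology
  names alone and makes scores batch-independent.

## The syntactic mappers

Five classical metrics are provided, each normalized so that 1 means
identical: Levenshtein (`1 - dist/max(|a|, |b|)`), indel
(`1 - dist/(|a| + |b|)`, insertions/deletions only), Jaro and
Jaro–Winkler (standard definitions; Winkler prefix scale 0.1, prefix
capped at 4), and Jaccard. The literature leaves the Jaccard token unit
open; here it operates on the same padded character 3-gram sets as the
TF-IDF mapper, which keeps `sim(x, x) = 1` even for strings shorter than
the gram size. Two empty strings compare as 1 by convention; one empty
string as 0. Levenshtein and indel distances are computed by
`utils::adist` (indel as unit insertion/deletion with substitution cost
2); Jaro and Jaro–Winkler are implemented in the package. The syntactic
mappers score each (query, name) pair pairwise — quadratic and therefore
slow on large ontologies — and share the exact ranking contract of the
TF-IDF mapper.

## Web annotators

The BioPortal Annotator returns no confidence scores, so every annotation
is reported with score 1. Zooma reports categorical confidence, converted
monotonically to HIGH = 1, GOOD = 0.75, MEDIUM = 0.5, LOW = 0.25 — the
numeric values are a package convention chosen to interleave sensibly
with the other mappers' [0, 1] scale. The HTTP transport is an injectable
function, requests are retried three times with exponential backoff, and
a persistently failing source term degrades to an unmapped entry with a
reason instead of aborting the run. These clients are exercised only
against recorded responses in the test suite.

## Mapping categorization

Given a tool mapping *T* and a benchmark mapping *H* for the same input,
the category is decided with precedence Same > MoreSpecific > MoreGeneral
> Sibling > Unrelated. Precedence matters in diamonds: if *T* is both an
ancestor and a co-sibling of *H*, the ancestry reading wins. Sibling uses
*asserted direct* parents only — inferred direct parents would require a
reasoner and are out of scope. Benchmarks are filtered to inputs with
exactly one distinct benchmark term before comparison (an ambiguous input
cannot indicate a single correct answer); inputs the tool left unmapped
are tallied separately rather than being counted as Unrelated, and
benchmark entries pointing at deprecated terms are kept but flagged.

## The fixture generator

`generateToyOntology()` emits a rooted class hierarchy as RDF/XML with a
label on every class, exact synonyms at rate 0.4, broad synonyms at rate
0.1, deprecation at rate 0.05, and a second parent at rate 0.15 (diamonds
that exercise closure and sibling logic). Labels are multi-word
pseudo-biomedical names built from syllable pools and disease-like tokens
("grihax fibrosis"), chosen so character n-gram statistics are
non-degenerate — uniform random strings would make every cosine score
close to 0 and the ranking tests vacuous. Generation is byte-deterministic
under its seed and never perturbs the caller's RNG state.
`corruptLabel()` applies seeded single-character edits to build
typo-corrupted query sets with a known true term.

What the generator does **not** emulate — and what passing tests
therefore do not show: real synonym distributions (EFO has terms with
dozens of synonyms), shared substrings between sibling labels
("type 1/type 2 diabetes"), multilingual labels, punctuation-heavy
clinical strings, and ontology-scale corpora (hundreds of thousands of
names). Results on real ontologies depend on those properties; the shipped
curated disease fixture covers a handful of them (synonym-mediated
matching, a deprecated duplicate, sibling and subclass confusions) by
hand.

## Verification and problem sizes

The test suite checks the mappers against independent brute-force oracles:
a dense TF-IDF + cosine computation over all pairs (agreement to 1e-9 in
score and exactly in ranking, ten seeded fixtures of 30–120 terms with 50
queries each), dynamic-programming and set-construction oracles for the
five string metrics (1000 seeded pairs each), a recursive DFS oracle for
the ancestor closure, and exhaustive enumeration for the categorizer on a
diamond fixture. Corruption robustness is pinned as a regression test: on
a 100-term fixture with one seeded character edit per query label, the
TF-IDF rank-1 refind rate must stay at or above 90%. These sizes keep the
whole suite under a minute per property while being large enough that the
sparse and dense code paths genuinely disagree when a contract is broken.

## Known limitations

* No OWL DL reasoning; entailment is the asserted-subclass closure.
* No concept recognition inside long passages — inputs are discrete
  entity descriptions, not documents.
* Turtle support covers the subset used by biomedical OWL exports
  (prefix declarations, predicate/object lists, typed and
  language-tagged literals, anonymous bnode lists); collections and
  multi-line literals are not parsed.
* Mapping types (`Exact`/`Broad`/`Narrow` in the output schema) default
  to `Exact`; assigning `Broad`/`Narrow` automatically would require the
  very hierarchy judgement the categorizer makes, and is left to curators.
* The TF-IDF scores of the default (shared-vocabulary) fit depend on the
  query batch; use `fitCorpusOnly = TRUE` when comparing scores across
  runs with different inputs.
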