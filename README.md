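# ontomatch

Maps free-text descriptions of biomedical entities — disease names,
phenotypes, cell types — to controlled terms in OWL ontologies, and
evaluates generated mappings against human-verified benchmark mappings.

Metadata in scientific repositories frequently describes the same entity
with syntactically different strings ("cardiac failure", "heart failure",
"myocardial failure"). Grounding such strings to terms in ontologies like
the Experimental Factor Ontology (EFO) or MONDO makes the data findable and
integrable. `ontomatch` does this grounding in bulk for curators and data
engineers, offline and reproducibly, from R or from the shell.

## Method

Every ontology term contributes its labels and exact synonyms (optionally
broad synonyms) to a **name corpus**. Strings are compared in one of two
ways:

* **TF-IDF character n-gram cosine** (default). A normalized string *s*
  becomes a sparse vector over its character n-grams (default *n* = 3,
  padded with one boundary space):
  *w(g, s) = tf(g, s) · idf(g)*, with smooth IDF
  *idf(g) = log((1 + N)/(1 + df(g))) + 1* over the *N* fitted documents,
  followed by ℓ₂ normalization. The score of a (query, name) pair is the
  cosine *q · d ∈ [0, 1]*, computed for the whole query batch as one sparse
  matrix product. Per query, scores are collapsed to the best name per
  term, ranked (ties broken by term IRI), filtered at `minScore` (default
  0.3) and truncated to `maxMappings` (default 3).
* **Syntactic distance metrics**: Levenshtein (1 − dist/max length), indel
  (1 − dist/(|a|+|b|)), Jaro, Jaro–Winkler (prefix scale 0.1, prefix ≤ 4)
  and Jaccard over character 3-gram sets — pairwise against every corpus
  name.

Clients for the **BioPortal Annotator** (every annotation scores 1) and
**Zooma** (HIGH = 1, GOOD = 0.75, MEDIUM = 0.5, LOW = 0.25) cover
repository-hosted ontologies.

For evaluation, a tool mapping *T* is compared with a human-verified
benchmark mapping *H* through the subclass hierarchy and categorized with
precedence **Same** (*T* = *H*), **More Specific** (*T* ⊑ *H*), **More
General** (*H* ⊑ *T*), **Sibling** (shared direct parent), else
**Unrelated**. Benchmarks are first filtered to inputs with exactly one
benchmark term, and deprecated ontology terms are kept out of the match
corpus while remaining visible to the categorizer.

## Worked example

```r
library(ontomatch)

fx  <- diseaseBenchmarkFixture()       # small disease ontology shipped with the package
idx <- loadOntology(fx$path)
tab <- mapTerms(c("heart attack", "Hayfever or allergic rhinitis", "zzqx"), idx)
tab
#> MappingTable: 3 mappings for 2 source terms; 1 unmapped
#>   mapper: tfidf
#>                     source_term                 term_label  term_curie     score
#> 1                  heart attack      myocardial infarction EFO:0000612 1.0000000
#> 2 Hayfever or allergic rhinitis          allergic rhinitis EFO:0005854 0.7005675
#> 3 Hayfever or allergic rhinitis seasonal allergic rhinitis EFO:0003956 0.5314527
```

"heart attack" reaches the term labelled *myocardial infarction* with score
1.0 through its exact synonym; the multi-word phrase ranks the general
*allergic rhinitis* above its seasonal subclass; "zzqx" shares no n-grams
with any name and is listed as unmapped with a reason. Comparing the
fixture's inputs against its encoded benchmark terms:

```r
tool <- mapTerms(fx$expected$input_text, idx)
benchmark <- data.frame(input_text = fx$expected$input_text,
                        iri = fx$expected$benchmark_iri)
compareMappingSets(tool, filterUnambiguous(benchmark), idx)
#> ComparisonReport over 6 categorized pairs
#>      category count percent
#>          Same     1   16.7%
#>  MoreSpecific     1   16.7%
#>   MoreGeneral     2   33.3%
#>       Sibling     1   16.7%
#>     Unrelated     1   16.7%
```

The same operations are available from the shell via the thin CLI:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ontomatch", package = "ontomatch"))')
Rscript "$CLI" map -s terms.txt -t ontology.owl -o mappings.csv --no-timestamp
Rscript "$CLI" compare --mappings mappings.csv --benchmark bench.tsv -t ontology.owl
```

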