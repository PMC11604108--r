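#' @import methods
NULL

# Each ontology term is stored as a plain list record inside the index:
#   iri, curie, labels, exact_synonyms, broad_synonyms, definitions,
#   parents, children, instances, deprecated, term_kind.
# Records are cheap, serialize to JSON directly, and avoid one S4 object
# per term in large ontologies.

#' Configuration for ontology loading
#'
#' Controls which terms are extracted from an OWL document and which
#' annotation properties are read.
#'
#' @slot termKindFilter one of `"classes"`, `"properties"`, `"both"`.
#' @slot includeBroadSynonyms include `oboInOwl:hasBroadSynonym` values.
#' @slot includeDeprecated keep deprecated terms in the matchable corpus
#'   (deprecated terms are always loaded and flagged, so the categorizer can
#'   resolve benchmark entries that point at obsolete terms).
#' @slot applyReasoning run the pluggable reasoning pre-step that may add
#'   inferred parent edges (off by default; the asserted hierarchy is used).
#' @slot baseIris character vector of IRI prefixes restricting extraction;
#'   empty means no restriction.
#' @slot extraLabelProps,extraSynonymProps,extraDefinitionProps additional
#'   annotation-property IRIs read on top of the built-in list.
#' @exportClass LoadConfig
setClass("LoadConfig", representation(
  termKindFilter = "character",
  includeBroadSynonyms = "logical",
  includeDeprecated = "logical",
  applyReasoning = "logical",
  baseIris = "character",
  extraLabelProps = "character",
  extraSynonymProps = "character",
  extraDefinitionProps = "character"
))

setValidity("LoadConfig", function(object) {
  if (!object@termKindFilter %in% c("classes", "properties", "both")) {
    return("termKindFilter must be one of 'classes', 'properties', 'both'")
  }
  TRUE
})

#' Create a LoadConfig
#'
#' @param termKindFilter map to ontology `"classes"`, `"properties"`, or
#'   `"both"`.
#' @param includeBroadSynonyms logical; also index broad synonyms.
#' @param includeDeprecated logical; keep deprecated terms matchable.
#' @param applyReasoning logical; apply the reasoning pre-step before the
#'   hierarchy is collected (default `FALSE`).
#' @param baseIris optional character vector of IRI prefixes to restrict
#'   extraction to.
#' @param extraLabelProps,extraSynonymProps,extraDefinitionProps extra
#'   annotation-property IRIs to read.
#' @return a `LoadConfig` object.
#' @examples
#' loadConfig(includeBroadSynonyms = TRUE)
#' @export
loadConfig <- function(termKindFilter = c("classes", "properties", "both"),
                       includeBroadSynonyms = FALSE,
                       includeDeprecated = FALSE,
                       applyReasoning = FALSE,
                       baseIris = character(),
                       extraLabelProps = character(),
                       extraSynonymProps = character(),
                       extraDefinitionProps = character()) {
  new("LoadConfig",
      termKindFilter = match.arg(termKindFilter),
      includeBroadSynonyms = includeBroadSynonyms,
      includeDeprecated = includeDeprecated,
      applyReasoning = applyReasoning,
      baseIris = as.character(baseIris),
      extraLabelProps = as.character(extraLabelProps),
      extraSynonymProps = as.character(extraSynonymProps),
      extraDefinitionProps = as.character(extraDefinitionProps))
}

#' Configuration for the mappers
#'
#' @slot mapper which mapper to use: `"tfidf"`, `"levenshtein"`, `"jaro"`,
#'   `"jarowinkler"`, `"jaccard"`, `"indel"`, `"bioportal"` or `"zooma"`.
#' @slot ngramSize character n-gram length for the TF-IDF vectorizer (and
#'   the Jaccard gram sets).
#' @slot maxMappings maximum number of candidate terms kept per source term.
#' @slot minScore minimum similarity score in `[0, 1]` for a candidate to be
#'   reported.
#' @slot fitCorpusOnly fit the TF-IDF vocabulary and IDF weights on the
#'   ontology name corpus only, rather than on the union of corpus and query
#'   batch (the default shares the vocabulary between both sides).
#' @exportClass MapperConfig
setClass("MapperConfig", representation(
  mapper = "character",
  ngramSize = "integer",
  maxMappings = "integer",
  minScore = "numeric",
  fitCorpusOnly = "logical"
))

.MAPPERS <- c("tfidf", "levenshtein", "jaro", "jarowinkler", "jaccard",
              "indel", "bioportal", "zooma")
.SYNTACTIC_METRICS <- c("levenshtein", "jaro", "jarowinkler", "jaccard",
                        "indel")

setValidity("MapperConfig", function(object) {
  msgs <- character()
  if (!object@mapper %in% .MAPPERS) {
    msgs <- c(msgs, paste0("unknown mapper '", object@mapper,
                           "'; valid mappers: ",
                           paste(.MAPPERS, collapse = ", ")))
  }
  if (object@ngramSize < 1L) msgs <- c(msgs, "ngramSize must be >= 1")
  if (object@maxMappings < 1L) msgs <- c(msgs, "maxMappings must be >= 1")
  if (object@minScore < 0 || object@minScore > 1) {
    msgs <- c(msgs, "minScore must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Create a MapperConfig
#'
#' @param mapper mapper name; see [MapperConfig-class].
#' @param ngramSize character n-gram length (default 3).
#' @param maxMappings candidates kept per source term (default 3).
#' @param minScore minimum reported score (default 0.3).
#' @param fitCorpusOnly fit IDF on the ontology names only (default `FALSE`).
#' @return a `MapperConfig` object.
#' @examples
#' mapperConfig("tfidf", maxMappings = 5)
#' @export
mapperConfig <- function(mapper = "tfidf", ngramSize = 3L, maxMappings = 3L,
                         minScore = 0.3, fitCorpusOnly = FALSE) {
  new("MapperConfig", mapper = as.character(mapper),
      ngramSize = as.integer(ngramSize),
      maxMappings = as.integer(maxMappings),
      minScore = as.numeric(minScore),
      fitCorpusOnly = fitCorpusOnly)
}

#' Processed target ontology
#'
#' Holds every extracted term, the load configuration, provenance, and a
#' memoized ancestor closure. Term records are reached with [getTerm()] and
#' friends rather than by slot access.
#'
#' @slot source the path or URL the ontology was loaded from.
#' @slot ontologyIri the ontology's own IRI, or `""`.
#' @slot version the `owl:versionInfo` / `owl:versionIRI` value, or `""`.
#' @slot terms named list of term records, keyed by IRI.
#' @slot loadConfig the [LoadConfig-class] used.
#' @slot closureCache environment memoizing IRI -> ancestor IRI sets.
#' @slot stats integer vector of extraction counters (anonymous parents
#'   skipped, dangling references dropped).
#' @exportClass OntologyIndex
setClass("OntologyIndex", representation(
  source = "character",
  ontologyIri = "character",
  version = "character",
  terms = "list",
  loadConfig = "LoadConfig",
  closureCache = "environment",
  stats = "integer"
))

setValidity("OntologyIndex", function(object) {
  iris <- names(object@terms)
  if (length(iris) && anyDuplicated(iris)) return("duplicate term IRIs")
  if (length(iris) && any(!nzchar(iris))) return("empty term IRI")
  TRUE
})

#' Table of generated term mappings
#'
#' The result of [mapTerms()]: one row per (source term, candidate ontology
#' term), grouped by source term in input order and sorted by descending
#' score within each source term, plus the source terms that received no
#' mapping at or above the score threshold.
#'
#' @slot rows `data.frame` with columns `source_id`, `source_term`,
#'   `term_label`, `term_curie`, `term_iri`, `score`, `mapper`,
#'   `mapping_type`, `tags`.
#' @slot unmapped `data.frame` with columns `source_id`, `source_term`,
#'   `reason`.
#' @slot metadata named list (ontology source, mapper, configuration,
#'   package version, optional timestamp).
#' @exportClass MappingTable
setClass("MappingTable", representation(
  rows = "data.frame",
  unmapped = "data.frame",
  metadata = "list"
))

setValidity("MappingTable", function(object) {
  need <- c("source_id", "source_term", "term_label", "term_curie",
            "term_iri", "score", "mapper", "mapping_type", "tags")
  if (!all(need %in% names(object@rows))) {
    return(paste("rows must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(object@rows) &&
      (any(object@rows$score < 0) || any(object@rows$score > 1))) {
    return("scores must lie in [0, 1]")
  }
  both <- intersect(object@rows$source_term, object@unmapped$source_term)
  if (length(both)) return("a source term cannot be both mapped and unmapped")
  TRUE
})

#' Benchmark comparison report
#'
#' Categorization of tool mappings against human-verified benchmark
#' mappings: per-pair categories plus aggregate counts and percentages.
#'
#' @slot counts named integer vector over the five categories.
#' @slot percents named numeric vector (percent of categorized pairs).
#' @slot pairs `data.frame` with columns `input_text`, `tool_iri`,
#'   `benchmark_iri`, `category`, `benchmark_deprecated`.
#' @slot excluded named integer vector: inputs dropped as ambiguous
#'   (several benchmark IRIs), unresolvable (IRI not in the index), or
#'   unmapped by the tool.
#' @exportClass ComparisonReport
setClass("ComparisonReport", representation(
  counts = "integer",
  percents = "numeric",
  pairs = "data.frame",
  excluded = "integer"
))

.CATEGORIES <- c("Same", "MoreSpecific", "MoreGeneral", "Sibling",
                 "Unrelated")

setValidity("ComparisonReport", function(object) {
  if (!identical(names(object@counts), .CATEGORIES)) {
    return("counts must be named by the five categories")
  }
  if (sum(object@counts) != nrow(object@pairs)) {
    return("counts must sum to the number of categorized pairs")
  }
  if (nrow(object@pairs) && abs(sum(object@percents) - 100) > 0.1) {
    return("percents must sum to 100")
  }
  TRUE
})
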