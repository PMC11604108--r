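#' Number of terms in an index
#' @param x an [OntologyIndex-class].
#' @return integer count of loaded terms.
#' @export
setGeneric("nTerms", function(x) standardGeneric("nTerms"))

#' IRIs of the loaded terms
#' @param x an [OntologyIndex-class].
#' @return character vector of term IRIs.
#' @export
setGeneric("termIRIs", function(x) standardGeneric("termIRIs"))

#' Retrieve one term record
#' @param x an [OntologyIndex-class].
#' @param iri term IRI.
#' @return a list with fields `iri`, `curie`, `labels`, `exact_synonyms`,
#'   `broad_synonyms`, `definitions`, `parents`, `children`, `instances`,
#'   `deprecated`, `term_kind`.
#' @export
setGeneric("getTerm", function(x, iri) standardGeneric("getTerm"))

#' All ancestors of a term
#'
#' Transitive closure of the asserted direct-parent relation, computed as a
#' fixpoint (cycle-safe) and memoized on the index. A term is not its own
#' ancestor unless it lies on a subclass cycle.
#'
#' @param x an [OntologyIndex-class].
#' @param iri term IRI; must be present in the index.
#' @return character vector of ancestor IRIs (possibly empty), sorted.
#' @examples
#' fx <- generateToyOntology(nTerms = 10, seed = 1)
#' idx <- loadOntology(fx$path)
#' ancestors(idx, termIRIs(idx)[1])
#' @export
setGeneric("ancestors", function(x, iri) standardGeneric("ancestors"))

#' Direct parents of a term
#' @param x an [OntologyIndex-class].
#' @param iri term IRI.
#' @return character vector of direct parent IRIs.
#' @export
setGeneric("parents", function(x, iri) standardGeneric("parents"))

#' Mapped rows of a mapping table
#' @param x a [MappingTable-class].
#' @return `data.frame` of mappings.
#' @export
setGeneric("mappingRows", function(x) standardGeneric("mappingRows"))

#' Source terms that received no mapping
#' @param x a [MappingTable-class].
#' @return `data.frame` of unmapped source terms.
#' @export
setGeneric("unmappedTerms", function(x) standardGeneric("unmappedTerms"))

#' Category counts of a comparison report
#' @param x a [ComparisonReport-class].
#' @return named integer vector over the five categories.
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))

#' Category percentages of a comparison report
#' @param x a [ComparisonReport-class].
#' @return named numeric vector summing to 100 over categorized pairs.
#' @export
setGeneric("categoryPercents", function(x) standardGeneric("categoryPercents"))
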