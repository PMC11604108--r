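# Accessors and show methods.

#' @rdname nTerms
#' @export
setMethod("nTerms", "OntologyIndex", function(x) length(x@terms))

#' @rdname termIRIs
#' @export
setMethod("termIRIs", "OntologyIndex", function(x) names(x@terms))

#' @rdname getTerm
#' @export
setMethod("getTerm", "OntologyIndex", function(x, iri) {
  term <- x@terms[[iri]]
  if (is.null(term)) omStop("unknown term IRI: ", iri)
  term
})

#' @rdname parents
#' @export
setMethod("parents", "OntologyIndex", function(x, iri) {
  getTerm(x, iri)$parents
})

#' @rdname ancestors
#' @export
setMethod("ancestors", "OntologyIndex", function(x, iri) {
  if (is.null(x@terms[[iri]])) omStop("unknown term IRI: ", iri)
  cached <- x@closureCache[[iri]]
  if (!is.null(cached)) return(cached)
  # Iterative fixpoint over direct parents; terminates on cycles because the
  # frontier only ever adds unseen IRIs.
  seen <- character()
  frontier <- x@terms[[iri]]$parents
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(lapply(new, function(p) {
      t <- x@terms[[p]]
      if (is.null(t)) character() else t$parents
    }), use.names = FALSE))
  }
  result <- sort(unique(seen))
  x@closureCache[[iri]] <- result
  result
})

setMethod("show", "OntologyIndex", function(object) {
  dep <- sum(vapply(object@terms, function(t) t$deprecated, logical(1)))
  cat("OntologyIndex with", length(object@terms), "terms",
      sprintf("(%d deprecated)\n", dep))
  cat("  source:", object@source, "\n")
  if (nzchar(object@ontologyIri)) cat("  ontology:", object@ontologyIri, "\n")
  if (nzchar(object@version)) cat("  version:", object@version, "\n")
  cat("  term kinds:", object@loadConfig@termKindFilter, "\n")
})

#' @rdname mappingRows
#' @export
setMethod("mappingRows", "MappingTable", function(x) x@rows)

#' @rdname unmappedTerms
#' @export
setMethod("unmappedTerms", "MappingTable", function(x) x@unmapped)

setMethod("show", "MappingTable", function(object) {
  n_src <- length(unique(object@rows$source_term))
  cat("MappingTable:", nrow(object@rows), "mappings for", n_src,
      "source terms;", nrow(object@unmapped), "unmapped\n")
  if (!is.null(object@metadata$mapper)) {
    cat("  mapper:", object@metadata$mapper, "\n")
  }
  if (!is.null(object@metadata$ontology_source)) {
    cat("  ontology:", object@metadata$ontology_source, "\n")
  }
  if (nrow(object@rows)) {
    print(utils::head(object@rows[, c("source_term", "term_label",
                                      "term_curie", "score")], 6))
    if (nrow(object@rows) > 6) cat("  ...\n")
  }
})

#' @rdname categoryCounts
#' @export
setMethod("categoryCounts", "ComparisonReport", function(x) x@counts)

#' @rdname categoryPercents
#' @export
setMethod("categoryPercents", "ComparisonReport", function(x) x@percents)

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport over", nrow(object@pairs), "categorized pairs\n")
  tab <- data.frame(
    category = names(object@counts),
    count = as.integer(object@counts),
    percent = sprintf("%.1f%%", object@percents)
  )
  print(tab, row.names = FALSE)
  if (any(object@excluded > 0)) {
    cat("excluded:",
        paste(names(object@excluded), object@excluded, sep = "=",
              collapse = ", "), "\n")
  }
})
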