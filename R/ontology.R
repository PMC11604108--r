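# Building an OntologyIndex from extracted triples.

isBlank <- function(x) startsWith(x, "_:")

#' Compact identifier for an IRI
#'
#' OBO PURLs (`.../obo/PREFIX_LOCAL`) and EFO IRIs (`.../efo/EFO_LOCAL`)
#' yield `PREFIX:LOCAL`; any other IRI yields `""` and the full IRI is used
#' in outputs.
#'
#' @param iri character vector of IRIs.
#' @return character vector of CURIEs (empty string where no rule applies).
#' @examples
#' iriToCurie("http://purl.obolibrary.org/obo/MONDO_0004975")
#' iriToCurie("http://www.ebi.ac.uk/efo/EFO_0000249")
#' @export
iriToCurie <- function(iri) {
  out <- character(length(iri))
  obo <- grepl("^http://purl\\.obolibrary\\.org/obo/[A-Za-z0-9]+_[A-Za-z0-9]+$",
               iri)
  out[obo] <- sub("^http://purl\\.obolibrary\\.org/obo/([A-Za-z0-9]+)_([A-Za-z0-9]+)$",
                  "\\1:\\2", iri[obo])
  efo <- grepl("^http://www\\.ebi\\.ac\\.uk/efo/EFO_[A-Za-z0-9]+$", iri)
  out[efo] <- sub("^http://www\\.ebi\\.ac\\.uk/efo/EFO_([A-Za-z0-9]+)$",
                  "EFO:\\1", iri[efo])
  out
}

# Fallback name for a term without labels or synonyms: the IRI local
# fragment with '_' and camelCase boundaries turned into spaces.
fallbackName <- function(iri) {
  local <- sub(".*[#/]", "", iri)
  local <- gsub("_", " ", local)
  local <- gsub("(?<=[a-z])(?=[A-Z])", " ", local, perl = TRUE)
  trimws(local)
}

#' Load an ontology into an index
#'
#' Reads an OWL document (RDF/XML or Turtle; local path or http(s) URL) and
#' extracts, per term, its labels (`rdfs:label`, `skos:prefLabel`), exact
#' synonyms (`oboInOwl:hasExactSynonym`, `NCIT:P90`, `EFO:alternative_term`),
#' broad synonyms (`oboInOwl:hasBroadSynonym`), definitions
#' (`skos:definition`, `IAO:0000115`), the asserted subclass hierarchy
#' (parents, children, instances) and the deprecation flag
#' (`owl:deprecated` or subclass of `oboInOwl:ObsoleteClass`).
#'
#' Anonymous classes (e.g. `owl:Restriction`) in parent position are skipped
#' and counted; hierarchy links pointing outside the extracted term set are
#' dropped and counted. A term with no label and no synonym receives a name
#' derived from its IRI fragment so that every term is matchable.
#'
#' @param source local file path or http(s) URL of the OWL document.
#' @param config a [LoadConfig-class]; defaults extract non-deprecated
#'   classes without broad synonyms and without reasoning.
#' @return an [OntologyIndex-class].
#' @examples
#' fx <- generateToyOntology(nTerms = 10, seed = 7)
#' idx <- loadOntology(fx$path)
#' idx
#' @export
loadOntology <- function(source, config = loadConfig()) {
  path <- resolveSource(source)
  parsed <- readTriples(path)
  tr <- parsed$triples
  if (!nrow(tr)) omStop("no terms extracted from ", source)

  if (config@applyReasoning) {
    reasoner <- getOption("ontomatch.reasoner", NULL)
    if (is.function(reasoner)) {
      extra <- reasoner(tr)
      if (is.data.frame(extra) && nrow(extra)) tr <- rbind(tr, extra)
    }
  }

  types <- tr[tr$predicate == IRI_TYPE & !tr$literal, c("subject", "object")]
  sub_cl <- tr[tr$predicate == IRI_SUBCLASS & !tr$literal,
               c("subject", "object")]
  sub_pr <- tr[tr$predicate == IRI_SUBPROP & !tr$literal,
               c("subject", "object")]

  class_iris <- unique(c(
    types$subject[types$object == IRI_OWL_CLASS],
    sub_cl$subject, sub_cl$object))
  class_iris <- class_iris[!isBlank(class_iris) &
                             class_iris != IRI_OBSOLETE_CLASS]
  prop_iris <- unique(c(
    types$subject[types$object %in% IRI_PROPERTY_TYPES],
    sub_pr$subject, sub_pr$object))
  prop_iris <- prop_iris[!isBlank(prop_iris)]
  prop_iris <- setdiff(prop_iris, class_iris)

  keep <- switch(config@termKindFilter,
                 classes = class_iris,
                 properties = prop_iris,
                 both = c(class_iris, prop_iris))
  if (length(config@baseIris)) {
    pat <- paste0("^(", paste(gsub("([.\\\\+*?\\[^\\]$(){}=!<>|:#-])",
                                   "\\\\\\1", config@baseIris),
                              collapse = "|"), ")")
    keep <- keep[grepl(pat, keep)]
  }
  keep <- unique(keep)
  if (!length(keep)) omStop("no terms extracted from ", source)

  label_props <- c(IRI_LABEL, IRI_PREFLABEL, config@extraLabelProps)
  exact_props <- c(IRI_EXACT_SYN, IRI_NCIT_SYN, IRI_EFO_SYN,
                   config@extraSynonymProps)
  def_props <- c(IRI_SKOS_DEF, IRI_IAO_DEF, config@extraDefinitionProps)

  lits <- tr[tr$literal, , drop = FALSE]
  getLits <- function(iri, props) {
    # document order within each property, rdfs:label values first
    unlist(lapply(props, function(p) {
      lits$object[lits$subject == iri & lits$predicate == p]
    }), use.names = FALSE) %||% character()
  }

  deprecated_iris <- unique(c(
    lits$subject[lits$predicate == IRI_DEPRECATED &
                   tolower(lits$object) == "true"],
    sub_cl$subject[sub_cl$object == IRI_OBSOLETE_CLASS]))

  # instances: typed by a class in the kept set
  inst <- types[!isBlank(types$subject) & types$object %in% keep, ,
                drop = FALSE]

  anon_parents <- sum(isBlank(sub_cl$object)) + sum(isBlank(sub_pr$object))
  dropped_refs <- 0L

  keep_set <- structure(rep(TRUE, length(keep)), names = keep)
  terms <- vector("list", length(keep))
  names(terms) <- keep
  for (iri in keep) {
    is_class <- iri %in% class_iris
    edges <- if (is_class) sub_cl else sub_pr
    par <- edges$object[edges$subject == iri]
    par <- par[!isBlank(par) & par != IRI_OBSOLETE_CLASS]
    chi <- edges$subject[edges$object == iri]
    chi <- chi[!isBlank(chi)]
    ins <- inst$subject[inst$object == iri]
    dropped_refs <- dropped_refs + sum(!par %in% keep) +
      sum(!chi %in% keep)
    par <- sort(unique(par[!is.na(keep_set[par])]))
    chi <- sort(unique(chi[!is.na(keep_set[chi])]))
    labels <- getLits(iri, label_props)
    exact <- getLits(iri, exact_props)
    broad <- getLits(iri, IRI_BROAD_SYN)
    if (!length(labels) && !length(exact)) labels <- fallbackName(iri)
    terms[[iri]] <- list(
      iri = iri,
      curie = iriToCurie(iri),
      labels = labels,
      exact_synonyms = unique(exact),
      broad_synonyms = unique(broad),
      definitions = getLits(iri, def_props),
      parents = par,
      children = chi,
      instances = sort(unique(ins)),
      deprecated = iri %in% deprecated_iris,
      term_kind = if (is_class) "class" else "property")
  }
  if (dropped_refs > 0) {
    warning(dropped_refs,
            " hierarchy reference(s) to IRIs outside the index dropped",
            call. = FALSE)
  }

  onto_subj <- types$subject[types$object == IRI_OWL_ONTOLOGY]
  onto_iri <- if (length(onto_subj) && !isBlank(onto_subj[1]))
    onto_subj[1] else ""
  version <- ""
  if (nzchar(onto_iri)) {
    v <- tr$object[tr$subject == onto_iri &
                     tr$predicate %in% c(IRI_VERSION_INFO, IRI_VERSION_IRI)]
    if (length(v)) version <- v[1]
  }

  new("OntologyIndex",
      source = as.character(source),
      ontologyIri = onto_iri,
      version = version,
      terms = terms,
      loadConfig = config,
      closureCache = new.env(parent = emptyenv()),
      stats = c(anonymous_parents_skipped = anon_parents,
                dangling_refs_dropped = dropped_refs))
}

#' Terms eligible for matching
#'
#' Deprecated terms are excluded from the matchable set unless the index was
#' loaded with `includeDeprecated = TRUE`; they remain in the index itself
#' so benchmark entries pointing at obsolete terms can still be categorized.
#'
#' @param index an [OntologyIndex-class].
#' @return character vector of matchable term IRIs.
#' @export
matchableIRIs <- function(index) {
  iris <- names(index@terms)
  if (index@loadConfig@includeDeprecated) return(iris)
  dep <- vapply(index@terms, function(t) t$deprecated, logical(1))
  iris[!dep]
}

#' Display label of a term
#'
#' The first label in document order, falling back to the first exact
#' synonym for label-less terms.
#'
#' @param index an [OntologyIndex-class].
#' @param iri term IRI.
#' @return a single string.
#' @export
termLabel <- function(index, iri) {
  term <- getTerm(index, iri)
  if (length(term$labels)) term$labels[1] else term$exact_synonyms[1]
}
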