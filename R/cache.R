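# On-disk ontology index cache: one directory per ontology source holding a
# metadata file and a serialized term table, both JSON. The layout is stable
# within a major version of the package; a major-version mismatch refuses to
# load and asks for a re-cache.

CACHE_META_FILE <- "metadata.json"
CACHE_TERMS_FILE <- "terms.json"

cacheMajorVersion <- function() {
  as.integer(unlist(utils::packageVersion("ontomatch"))[1])
}

loadConfigToList <- function(config) {
  list(
    term_kind_filter = config@termKindFilter,
    include_broad_synonyms = config@includeBroadSynonyms,
    include_deprecated = config@includeDeprecated,
    apply_reasoning = config@applyReasoning,
    base_iris = as.list(config@baseIris),
    extra_label_props = as.list(config@extraLabelProps),
    extra_synonym_props = as.list(config@extraSynonymProps),
    extra_definition_props = as.list(config@extraDefinitionProps))
}

loadConfigFromList <- function(x) {
  loadConfig(
    termKindFilter = x$term_kind_filter,
    includeBroadSynonyms = isTRUE(x$include_broad_synonyms),
    includeDeprecated = isTRUE(x$include_deprecated),
    applyReasoning = isTRUE(x$apply_reasoning),
    baseIris = as.character(unlist(x$base_iris)),
    extraLabelProps = as.character(unlist(x$extra_label_props)),
    extraSynonymProps = as.character(unlist(x$extra_synonym_props)),
    extraDefinitionProps = as.character(unlist(x$extra_definition_props)))
}

#' Save an ontology index to a cache directory
#'
#' @param index an [OntologyIndex-class].
#' @param dir directory to write to (created if missing).
#' @return the cache directory path, invisibly.
#' @seealso [loadOntologyCache()]
#' @examples
#' fx <- generateToyOntology(nTerms = 8, seed = 3)
#' idx <- loadOntology(fx$path)
#' d <- saveOntologyCache(idx, file.path(tempdir(), "toy-cache"))
#' idx2 <- loadOntologyCache(d)
#' @export
saveOntologyCache <- function(index, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list(
    artifact = "ontomatch",
    artifact_version = as.character(utils::packageVersion("ontomatch")),
    cache_major_version = cacheMajorVersion(),
    source = index@source,
    ontology_iri = index@ontologyIri,
    ontology_version = index@version,
    load_config = loadConfigToList(index@loadConfig),
    stats = as.list(index@stats))
  jsonlite::write_json(meta, file.path(dir, CACHE_META_FILE),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(unname(index@terms), file.path(dir, CACHE_TERMS_FILE),
                       auto_unbox = FALSE)
  invisible(dir)
}

#' Load an ontology index from a cache directory
#'
#' Round-trips with [saveOntologyCache()]: the loaded index has the same
#' term records, load configuration and closure behaviour as the saved one.
#'
#' @param dir a directory written by [saveOntologyCache()] with the same
#'   major version of the package.
#' @return an [OntologyIndex-class].
#' @export
loadOntologyCache <- function(dir) {
  meta_path <- file.path(dir, CACHE_META_FILE)
  terms_path <- file.path(dir, CACHE_TERMS_FILE)
  if (!file.exists(meta_path) || !file.exists(terms_path)) {
    omStop("missing cache files in ", dir)
  }
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(meta$artifact, "ontomatch") ||
      !identical(as.integer(meta$cache_major_version), cacheMajorVersion())) {
    omStop("cache in ", dir, " was written by an incompatible version; ",
           "please re-cache the ontology")
  }
  raw <- jsonlite::fromJSON(terms_path, simplifyVector = FALSE)
  chr <- function(x) as.character(unlist(x))
  terms <- lapply(raw, function(t) {
    list(iri = chr(t$iri), curie = chr(t$curie), labels = chr(t$labels),
         exact_synonyms = chr(t$exact_synonyms),
         broad_synonyms = chr(t$broad_synonyms),
         definitions = chr(t$definitions), parents = chr(t$parents),
         children = chr(t$children), instances = chr(t$instances),
         deprecated = isTRUE(unlist(t$deprecated)),
         term_kind = chr(t$term_kind))
  })
  names(terms) <- vapply(terms, function(t) t$iri, character(1))
  new("OntologyIndex",
      source = meta$source %||% "",
      ontologyIri = meta$ontology_iri %||% "",
      version = meta$ontology_version %||% "",
      terms = terms,
      loadConfig = loadConfigFromList(meta$load_config),
      closureCache = new.env(parent = emptyenv()),
      stats = c(anonymous_parents_skipped =
                  as.integer(meta$stats$anonymous_parents_skipped %||% 0L),
                dangling_refs_dropped =
                  as.integer(meta$stats$dangling_refs_dropped %||% 0L)))
}
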