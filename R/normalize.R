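#' Normalize a string for matching
#'
#' Lowercases, applies Unicode NFC normalization, collapses runs of
#' whitespace to single spaces and strips leading/trailing space. No tokens
#' are removed: in particular negation prefixes such as "non" are kept, so
#' "non-hodgkin's lymphoma" does not degrade to "hodgkin's lymphoma" — a
#' known failure mode of stop-word-based preprocessing.
#'
#' @param text character vector.
#' @return character vector of the same length.
#' @examples
#' normalizeText("Heart  Failure ")
#' normalizeText("non-Hodgkin's lymphoma")
#' @export
normalizeText <- function(text) {
  out <- stringi::stri_trans_nfc(as.character(text))
  out <- stringi::stri_trans_tolower(out)
  out <- gsub("\\s+", " ", out)
  trimws(out)
}

#' Build the name corpus of an index
#'
#' One entry per normalized label and exact synonym of every matchable term
#' (deprecated terms are excluded unless the index was loaded with
#' `includeDeprecated = TRUE`); broad synonyms are appended when
#' `includeBroad`. Duplicate names within a term (e.g. a synonym equal to
#' the label after normalization) are collapsed to one entry, keeping the
#' strongest kind (label over exact synonym over broad synonym). Entries are
#' ordered by term IRI, then name, so corpus construction is deterministic.
#'
#' @param index an [OntologyIndex-class].
#' @param includeBroad include broad synonyms; defaults to the index's load
#'   configuration.
#' @return `data.frame` with columns `term_iri`, `name`, `name_kind`.
#' @examples
#' fx <- generateToyOntology(nTerms = 10, seed = 7)
#' head(buildNameCorpus(loadOntology(fx$path)))
#' @export
buildNameCorpus <- function(index,
                            includeBroad =
                              index@loadConfig@includeBroadSynonyms) {
  iris <- matchableIRIs(index)
  pieces <- lapply(iris, function(iri) {
    term <- index@terms[[iri]]
    name <- c(term$labels, term$exact_synonyms,
              if (includeBroad) term$broad_synonyms)
    kind <- c(rep("label", length(term$labels)),
              rep("exact_synonym", length(term$exact_synonyms)),
              if (includeBroad)
                rep("broad_synonym", length(term$broad_synonyms)))
    data.frame(term_iri = rep(iri, length(name)), name = name,
               name_kind = kind, stringsAsFactors = FALSE)
  })
  corpus <- do.call(rbind, pieces)
  if (is.null(corpus) || !nrow(corpus)) omStop("no matchable names")
  corpus$name <- normalizeText(corpus$name)
  corpus <- corpus[nzchar(corpus$name), , drop = FALSE]
  if (!nrow(corpus)) omStop("no matchable names")
  # kind priority keeps the label entry when a synonym duplicates it
  kind_rank <- match(corpus$name_kind,
                     c("label", "exact_synonym", "broad_synonym"))
  corpus <- corpus[order(corpus$term_iri, corpus$name, kind_rank), ,
                   drop = FALSE]
  corpus <- corpus[!duplicated(corpus[c("term_iri", "name")]), , drop = FALSE]
  rownames(corpus) <- NULL
  corpus
}

#' Coerce source-term input to the canonical data.frame
#'
#' Accepts a character vector or a data.frame with a `text` column (optional
#' `source_id`, `tags`).
#' @noRd
asSourceTerms <- function(sources) {
  if (is.character(sources)) {
    sources <- data.frame(text = sources, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(sources) || !"text" %in% names(sources)) {
    omStop("sources must be a character vector or a data.frame ",
           "with a 'text' column")
  }
  sources$text <- trimws(as.character(sources$text))
  if (is.null(sources$source_id)) sources$source_id <- NA_character_
  if (is.null(sources$tags)) sources$tags <- ""
  if (any(!nzchar(sources$text))) {
    omStop("source terms must be non-empty after stripping whitespace")
  }
  ids <- sources$source_id[!is.na(sources$source_id)]
  if (anyDuplicated(ids)) omStop("duplicate source term ids")
  rownames(sources) <- NULL
  sources[c("text", "source_id", "tags")]
}
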