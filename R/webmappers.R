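# Clients for the BioPortal Annotator and Zooma annotation web services.
#
# The HTTP transport is an injectable function(url, query) -> list(status,
# text) so the clients can be exercised against recorded responses without
# network access; the default transport uses httr. Failed requests are
# retried with exponential backoff (3 attempts); a persistently failing
# source term is recorded as a per-source failure and the run continues.

BIOPORTAL_ANNOTATOR_URL <- "https://data.bioontology.org/annotator"
ZOOMA_ANNOTATE_URL <-
  "https://www.ebi.ac.uk/spot/zooma/v2/api/services/annotate"

# Zooma reports categorical confidence, not numeric scores; this monotone
# table turns it into scores on the same [0, 1] scale as the other mappers.
ZOOMA_CONFIDENCE_SCORES <- c(HIGH = 1.0, GOOD = 0.75, MEDIUM = 0.5,
                             LOW = 0.25)

#' Default HTTP transport
#'
#' @return a `function(url, query)` returning `list(status, text)`.
#' @export
httrTransport <- function() {
  function(url, query) {
    resp <- httr::GET(url, query = query)
    list(status = httr::status_code(resp),
         text = httr::content(resp, as = "text", encoding = "UTF-8"))
  }
}

# Shared retry loop. Returns list(ok, parsed/reason).
requestWithRetry <- function(transport, url, query, maxAttempts = 3L,
                             backoffBase = 1) {
  for (attempt in seq_len(maxAttempts)) {
    result <- tryCatch(transport(url, query),
                       error = function(e) {
                         list(status = NA_integer_,
                              text = conditionMessage(e))
                       })
    status <- result$status
    if (!is.na(status) && status >= 200L && status < 300L) {
      parsed <- tryCatch(jsonlite::fromJSON(result$text,
                                            simplifyVector = FALSE),
                         error = function(e) NULL)
      if (is.null(parsed)) {
        return(list(ok = FALSE, reason = "unparseable response body"))
      }
      return(list(ok = TRUE, parsed = parsed, retried = attempt > 1L))
    }
    if (attempt < maxAttempts) {
      Sys.sleep(backoffBase * 2^(attempt - 1L))
    }
  }
  list(ok = FALSE,
       reason = paste0("request failed after ", maxAttempts, " attempts",
                       if (!is.na(status)) paste0(" (HTTP ", status, ")")))
}

emptyRawMatches <- function() {
  data.frame(source_index = integer(), term_iri = character(),
             matched_name = character(), name_kind = character(),
             score = numeric(), stringsAsFactors = FALSE)
}

webRawMatches <- function(per_source, failures) {
  out <- if (length(per_source)) do.call(rbind, per_source)
         else emptyRawMatches()
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(failures)) {
    do.call(rbind, failures)
  } else {
    data.frame(source_index = integer(), reason = character(),
               stringsAsFactors = FALSE)
  }
  out
}

#' Map source terms with the BioPortal Annotator
#'
#' Calls the BioPortal Annotator REST API for each source term, restricted
#' to one ontology. BioPortal does not return confidence scores, so every
#' returned annotation is a match with score 1.
#'
#' @param sources character vector or source-term data.frame.
#' @param ontologyAcronym ontology acronym as used by BioPortal (e.g.
#'   `"EFO"`).
#' @param config a [MapperConfig-class]; `maxMappings` truncates the
#'   annotations kept per source.
#' @param apiKey BioPortal API key; defaults to the `BIOPORTAL_API_KEY`
#'   environment variable. Missing key is a fatal error before any request.
#' @param transport HTTP transport function (see [httrTransport()]).
#' @param backoffBase base seconds for the exponential retry backoff.
#' @return raw-match `data.frame` as from [tfidfMap()]; per-source request
#'   failures are attached as the `"failures"` attribute.
#' @export
bioportalMap <- function(sources, ontologyAcronym,
                         config = mapperConfig("bioportal"),
                         apiKey = Sys.getenv("BIOPORTAL_API_KEY"),
                         transport = httrTransport(), backoffBase = 1) {
  sources <- asSourceTerms(sources)
  if (!nzchar(apiKey)) {
    omStop("a BioPortal API key is required (set BIOPORTAL_API_KEY)")
  }
  per_source <- list(); failures <- list()
  for (i in seq_len(nrow(sources))) {
    res <- requestWithRetry(transport, BIOPORTAL_ANNOTATOR_URL,
                            query = list(text = sources$text[i],
                                         ontologies = ontologyAcronym,
                                         apikey = apiKey),
                            backoffBase = backoffBase)
    if (!res$ok) {
      failures[[length(failures) + 1L]] <-
        data.frame(source_index = i, reason = res$reason,
                   stringsAsFactors = FALSE)
      next
    }
    anns <- res$parsed
    if (!length(anns)) next
    iris <- vapply(anns, function(a) {
      a$annotatedClass$`@id` %||% NA_character_
    }, character(1))
    labs <- vapply(anns, function(a) {
      a$annotatedClass$prefLabel %||% ""
    }, character(1))
    keep <- !is.na(iris)
    iris <- iris[keep]; labs <- labs[keep]
    if (!length(iris)) next
    dedup <- !duplicated(iris)
    iris <- iris[dedup]; labs <- labs[dedup]
    take <- seq_len(min(length(iris), config@maxMappings))
    per_source[[length(per_source) + 1L]] <- data.frame(
      source_index = i, term_iri = iris[take], matched_name = labs[take],
      name_kind = "label", score = 1, stringsAsFactors = FALSE)
  }
  webRawMatches(per_source, failures)
}

#' Map source terms with the Zooma annotator
#'
#' Calls the Zooma annotation service for each source term, restricted to
#' one OLS ontology. Zooma's categorical confidence labels are converted to
#' numeric scores (HIGH = 1, GOOD = 0.75, MEDIUM = 0.5, LOW = 0.25).
#'
#' @inheritParams bioportalMap
#' @param ontologyName ontology name as used by OLS (e.g. `"efo"`).
#' @return raw-match `data.frame`; see [bioportalMap()].
#' @export
zoomaMap <- function(sources, ontologyName,
                     config = mapperConfig("zooma"),
                     transport = httrTransport(), backoffBase = 1) {
  sources <- asSourceTerms(sources)
  per_source <- list(); failures <- list()
  for (i in seq_len(nrow(sources))) {
    res <- requestWithRetry(transport, ZOOMA_ANNOTATE_URL,
                            query = list(propertyValue = sources$text[i],
                                         filter = sprintf(
                                           "required:[none],ontologies:[%s]",
                                           ontologyName)),
                            backoffBase = backoffBase)
    if (!res$ok) {
      failures[[length(failures) + 1L]] <-
        data.frame(source_index = i, reason = res$reason,
                   stringsAsFactors = FALSE)
      next
    }
    items <- res$parsed
    if (!length(items)) next
    rows <- lapply(items, function(item) {
      tags <- unlist(item$semanticTags, use.names = FALSE)
      if (!length(tags)) return(NULL)
      conf <- toupper(item$confidence %||% "LOW")
      score <- if (conf %in% names(ZOOMA_CONFIDENCE_SCORES))
        ZOOMA_CONFIDENCE_SCORES[[conf]] else 0.25
      label <- item$annotatedProperty$propertyValue %||% ""
      data.frame(source_index = i, term_iri = tags, matched_name = label,
                 name_kind = "label", score = score,
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(rows) || !nrow(rows)) next
    rows <- rows[order(-rows$score, rows$term_iri), , drop = FALSE]
    rows <- rows[!duplicated(rows$term_iri), , drop = FALSE]
    rows <- rows[rows$score >= config@minScore, , drop = FALSE]
    rows <- utils::head(rows, config@maxMappings)
    if (nrow(rows)) per_source[[length(per_source) + 1L]] <- rows
  }
  webRawMatches(per_source, failures)
}
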