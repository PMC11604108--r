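# Reading source terms, orchestrating end-to-end mapping, and reading and
# writing the mapping table.

MAPPING_COLUMNS <- c("Source Term ID", "Source Term", "Mapped Term Label",
                     "Mapped Term CURIE", "Mapped Term IRI", "Mapping Score",
                     "Mapper", "Mapping Type", "Tags")

#' Read source terms from a file
#'
#' Without a delimiter, the file is a line-separated list: one source term
#' per non-empty line. With a delimiter it is a table (e.g. CSV or TSV) and
#' terms come from `column` (name or 1-based index); `idColumn` optionally
#' names a column of source-term identifiers.
#'
#' @param path input file.
#' @param delimiter single delimiter character, or `NULL` for line mode.
#' @param column column name or index holding the terms (table mode;
#'   default first column).
#' @param idColumn optional column name or index of term identifiers.
#' @return `data.frame` with columns `text`, `source_id`, `tags`, in file
#'   order.
#' @examples
#' f <- tempfile(); writeLines(c("asthma", "", "heart attack"), f)
#' readSourceTerms(f)
#' @export
readSourceTerms <- function(path, delimiter = NULL, column = 1L,
                            idColumn = NULL) {
  if (!file.exists(path)) omStop("cannot read source terms file: ", path)
  if (is.null(delimiter)) {
    lines <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
    lines <- lines[nzchar(lines)]
    if (!length(lines)) omStop("no source terms in ", path)
    return(data.frame(text = lines, source_id = NA_character_, tags = "",
                      stringsAsFactors = FALSE))
  }
  tab <- utils::read.table(path, sep = delimiter, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  pick <- function(col, what) {
    if (is.numeric(col)) {
      if (col > ncol(tab)) {
        omStop(what, " column ", col, " out of range; file has ",
               ncol(tab), " columns")
      }
      return(tab[[col]])
    }
    if (!col %in% names(tab)) {
      omStop(what, " column '", col, "' not found; available columns: ",
             paste(names(tab), collapse = ", "))
    }
    tab[[col]]
  }
  text <- trimws(as.character(pick(column, "term")))
  ids <- if (is.null(idColumn)) rep(NA_character_, length(text))
         else as.character(pick(idColumn, "id"))
  keep <- nzchar(text)
  if (!any(keep)) omStop("no source terms in ", path)
  data.frame(text = text[keep], source_id = ids[keep], tags = "",
             stringsAsFactors = FALSE)
}

# Resolve the ontology argument of mapTerms: an OntologyIndex passes
# through, a cache directory is loaded from cache, anything else is loaded
# as an OWL document.
resolveOntology <- function(ontology, config) {
  if (is(ontology, "OntologyIndex")) return(ontology)
  if (is.character(ontology) && dir.exists(ontology) &&
      file.exists(file.path(ontology, CACHE_META_FILE))) {
    return(loadOntologyCache(ontology))
  }
  loadOntology(ontology, config)
}

#' Map source terms to an ontology
#'
#' The single entry point: loads (or reuses) the target ontology, builds
#' the name corpus, dispatches to the configured mapper and assembles a
#' [MappingTable-class]. Source terms with no match at or above the score
#' threshold appear in the unmapped listing when `includeUnmapped`.
#'
#' @param sources character vector, data.frame from [readSourceTerms()], or
#'   any data.frame with a `text` column.
#' @param ontology an [OntologyIndex-class], a path/URL to an OWL document,
#'   or a cache directory written by [saveOntologyCache()]. For the web
#'   mappers (`"bioportal"`, `"zooma"`) this is the ontology acronym in the
#'   respective repository.
#' @param mapperConfig a [MapperConfig-class].
#' @param loadConfig a [LoadConfig-class] (ignored when `ontology` is
#'   already an index or a cache).
#' @param includeUnmapped keep unmapped source terms in the table.
#' @param timestamp record a timestamp in the metadata; disable for
#'   byte-reproducible outputs.
#' @param ... passed to the web mappers (e.g. `apiKey`, `transport`).
#' @return a [MappingTable-class].
#' @examples
#' fx <- generateToyOntology(nTerms = 20, seed = 7)
#' tab <- mapTerms(fixtureQueries(fx)$query[1:5], fx$path)
#' tab
#' @export
mapTerms <- function(sources, ontology,
                     mapperConfig = ontomatch::mapperConfig(),
                     loadConfig = ontomatch::loadConfig(),
                     includeUnmapped = TRUE, timestamp = FALSE, ...) {
  sources <- asSourceTerms(sources)
  web <- mapperConfig@mapper %in% c("bioportal", "zooma")
  failures <- NULL
  if (web) {
    matches <- if (mapperConfig@mapper == "bioportal") {
      bioportalMap(sources, ontology, mapperConfig, ...)
    } else {
      zoomaMap(sources, ontology, mapperConfig, ...)
    }
    failures <- attr(matches, "failures")
    labelOf <- function(iri, fallback) fallback
    curieOf <- iriToCurie
    ontology_source <- paste0(mapperConfig@mapper, ":", ontology)
  } else {
    index <- resolveOntology(ontology, loadConfig)
    corpus <- buildNameCorpus(index)
    matches <- if (mapperConfig@mapper == "tfidf") {
      tfidfMap(sources, corpus, mapperConfig)
    } else {
      syntacticMap(sources, corpus, mapperConfig)
    }
    labelOf <- function(iri, fallback) {
      vapply(iri, function(x) termLabel(index, x), character(1))
    }
    curieOf <- function(iri) {
      vapply(iri, function(x) index@terms[[x]]$curie, character(1))
    }
    ontology_source <- index@source
  }

  if (nrow(matches)) {
    rows <- data.frame(
      source_id = sources$source_id[matches$source_index],
      source_term = sources$text[matches$source_index],
      term_label = unname(labelOf(matches$term_iri, matches$matched_name)),
      term_curie = unname(curieOf(matches$term_iri)),
      term_iri = matches$term_iri,
      score = matches$score,
      mapper = mapperConfig@mapper,
      mapping_type = "Exact",
      tags = sources$tags[matches$source_index],
      stringsAsFactors = FALSE)
    # group by source term in input order; within-source rank order is
    # preserved because order() is stable
    rows <- rows[order(matches$source_index), , drop = FALSE]
    rownames(rows) <- NULL
  } else {
    rows <- emptyMappingRows()
  }

  unmapped <- emptyUnmappedRows()
  if (includeUnmapped) {
    missing_idx <- setdiff(seq_len(nrow(sources)),
                           unique(matches$source_index))
    if (length(missing_idx)) {
      reason <- rep("no match at or above the score threshold",
                    length(missing_idx))
      if (!is.null(failures) && nrow(failures)) {
        hit <- match(missing_idx, failures$source_index)
        reason[!is.na(hit)] <- failures$reason[hit[!is.na(hit)]]
      }
      unmapped <- data.frame(
        source_id = sources$source_id[missing_idx],
        source_term = sources$text[missing_idx],
        reason = reason, stringsAsFactors = FALSE)
    }
  }

  metadata <- list(
    ontology_source = ontology_source,
    mapper = mapperConfig@mapper,
    ngram_size = mapperConfig@ngramSize,
    max_mappings = mapperConfig@maxMappings,
    min_score = mapperConfig@minScore,
    artifact = "ontomatch",
    artifact_version = as.character(utils::packageVersion("ontomatch")))
  if (timestamp) metadata$timestamp <- format(Sys.time(), tz = "UTC")

  new("MappingTable", rows = rows, unmapped = unmapped, metadata = metadata)
}

emptyMappingRows <- function() {
  data.frame(source_id = character(), source_term = character(),
             term_label = character(), term_curie = character(),
             term_iri = character(), score = numeric(),
             mapper = character(), mapping_type = character(),
             tags = character(), stringsAsFactors = FALSE)
}

emptyUnmappedRows <- function() {
  data.frame(source_id = character(), source_term = character(),
             reason = character(), stringsAsFactors = FALSE)
}

#' Write a mapping table to CSV or TSV
#'
#' Metadata is written as `# key: value` header lines, followed by a header
#' row and one data row per mapping; unmapped source terms (when present in
#' the table) get rows with empty mapped-term fields. Scores are printed
#' with six decimal places. The output round-trips through
#' [readMappingTable()].
#'
#' @param table a [MappingTable-class].
#' @param path output file.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeMappingTable <- function(table, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  meta <- table@metadata
  header <- vapply(names(meta), function(k) {
    sprintf("# %s: %s", k, as.character(meta[[k]]))
  }, character(1))
  rows <- table@rows
  out <- data.frame(
    a = ifelse(is.na(rows$source_id), "", rows$source_id),
    b = rows$source_term,
    c = rows$term_label, d = rows$term_curie, e = rows$term_iri,
    f = sprintf("%.6f", rows$score), g = rows$mapper,
    h = rows$mapping_type, i = rows$tags, stringsAsFactors = FALSE)
  if (nrow(table@unmapped)) {
    un <- table@unmapped
    out <- rbind(out, data.frame(
      a = ifelse(is.na(un$source_id), "", un$source_id),
      b = un$source_term, c = "", d = "", e = "", f = "", g = "",
      h = "", i = "", stringsAsFactors = FALSE))
  }
  names(out) <- MAPPING_COLUMNS
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) omStop("cannot write to ", path))
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(out, con, sep = sep, row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a mapping table
#'
#' Reads either the format written by [writeMappingTable()] (metadata
#' header lines prefixed with `#`, then the nine mapping columns) or an
#' SSSOM-style TSV with at least `subject_id` and `object_id` columns, in
#' which case rows become mappings with `mapper = "external"` and score 1.
#'
#' @param path input file.
#' @param format `"csv"` or `"tsv"`; default guesses from the extension.
#' @return a [MappingTable-class].
#' @export
readMappingTable <- function(path, format = NULL) {
  if (!file.exists(path)) omStop("cannot read mapping table: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.tsv$|\\.sssom(\\.tsv)?$", path)) "tsv" else "csv"
  }
  sep <- if (format == "csv") "," else "\t"
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  metadata <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([^:]+):\\s*(.*)$", ml))[[1]]
    if (length(m) == 3) metadata[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (!length(body)) omStop("mapping table ", path, " has no header row")
  tab <- utils::read.table(text = body, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "",
                           colClasses = "character")
  if (all(MAPPING_COLUMNS[1:8] %in% names(tab))) {
    mapped <- nzchar(tab[["Mapped Term IRI"]])
    rows <- data.frame(
      source_id = ifelse(nzchar(tab[["Source Term ID"]][mapped]),
                         tab[["Source Term ID"]][mapped], NA_character_),
      source_term = tab[["Source Term"]][mapped],
      term_label = tab[["Mapped Term Label"]][mapped],
      term_curie = tab[["Mapped Term CURIE"]][mapped],
      term_iri = tab[["Mapped Term IRI"]][mapped],
      score = as.numeric(tab[["Mapping Score"]][mapped]),
      mapper = tab[["Mapper"]][mapped],
      mapping_type = tab[["Mapping Type"]][mapped],
      tags = if ("Tags" %in% names(tab)) tab[["Tags"]][mapped]
             else rep("", sum(mapped)),
      stringsAsFactors = FALSE)
    unmapped <- data.frame(
      source_id = ifelse(nzchar(tab[["Source Term ID"]][!mapped]),
                         tab[["Source Term ID"]][!mapped], NA_character_),
      source_term = tab[["Source Term"]][!mapped],
      reason = rep("unmapped in source table", sum(!mapped)),
      stringsAsFactors = FALSE)
    if (!nrow(rows) && !nrow(unmapped)) {
      warning("mapping table ", path, " contains no data rows",
              call. = FALSE)
    }
    return(new("MappingTable", rows = rows,
               unmapped = unmapped, metadata = metadata))
  }
  if (all(c("subject_id", "object_id") %in% names(tab))) {
    if (!nrow(tab)) {
      warning("mapping table ", path, " contains no data rows",
              call. = FALSE)
    }
    rows <- data.frame(
      source_id = tab$subject_id,
      source_term = if ("subject_label" %in% names(tab)) tab$subject_label
                    else tab$subject_id,
      term_label = if ("object_label" %in% names(tab)) tab$object_label
                   else rep("", nrow(tab)),
      term_curie = ifelse(grepl("^https?://", tab$object_id),
                          iriToCurie(tab$object_id), tab$object_id),
      term_iri = tab$object_id,
      score = rep(1, nrow(tab)), mapper = rep("external", nrow(tab)),
      mapping_type = rep("Exact", nrow(tab)), tags = rep("", nrow(tab)),
      stringsAsFactors = FALSE)
    return(new("MappingTable", rows = rows, unmapped = emptyUnmappedRows(),
               metadata = list(source = path, mapper = "external")))
  }
  omStop("unrecognized mapping table schema in ", path,
         "; detected columns: ", paste(names(tab), collapse = ", "))
}
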