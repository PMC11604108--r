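# Benchmark evaluation: filter benchmark mapping sets to unambiguous
# entries and categorize each tool mapping T against the human-verified
# mapping H through the ontology class hierarchy.

#' Filter a benchmark to unambiguous entries
#'
#' Keeps only input texts with exactly one distinct benchmark IRI — a
#' singular mapping is unambiguous evidence that one and only one term was
#' the appropriate annotation for the input. Repeated (input, IRI) rows are
#' deduplicated to one entry.
#'
#' @param benchmark `data.frame` with columns `input_text` and `iri`.
#' @return `data.frame` with columns `input_text`, `iri`; the number of
#'   inputs excluded as ambiguous is attached as attribute
#'   `"excluded_ambiguous"`.
#' @examples
#' b <- data.frame(input_text = c("x", "x", "y", "y"),
#'                 iri = c("A", "B", "C", "C"))
#' filterUnambiguous(b)  # keeps y only
#' @export
filterUnambiguous <- function(benchmark) {
  if (!all(c("input_text", "iri") %in% names(benchmark))) {
    omStop("benchmark must have columns 'input_text' and 'iri'")
  }
  benchmark <- unique(benchmark[c("input_text", "iri")])
  n_distinct <- table(benchmark$input_text)
  ambiguous <- names(n_distinct)[n_distinct > 1]
  kept <- benchmark[!benchmark$input_text %in% ambiguous, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "excluded_ambiguous") <- length(ambiguous)
  kept
}

#' Categorize a tool mapping against a benchmark mapping
#'
#' Compares tool term T with benchmark term H through the subclass
#' hierarchy of the index, with precedence Same > MoreSpecific >
#' MoreGeneral > Sibling (a pair can satisfy several clauses, e.g. in a
#' diamond where a parent is also reachable as a sibling):
#'
#' * `Same` — T and H are the same term.
#' * `MoreSpecific` — T is a subclass of H (H is an ancestor of T).
#' * `MoreGeneral` — T is a superclass of H.
#' * `Sibling` — T and H share at least one direct parent.
#' * `Unrelated` — none of the above.
#'
#' Entailment is approximated by the transitive closure over asserted
#' subclass edges (plus any edges the reasoning pre-step added at load
#' time).
#'
#' @param index an [OntologyIndex-class] containing both terms.
#' @param tIri tool-mapped term IRI.
#' @param hIri benchmark term IRI.
#' @return one of `"Same"`, `"MoreSpecific"`, `"MoreGeneral"`,
#'   `"Sibling"`, `"Unrelated"`.
#' @examples
#' fx <- diseaseBenchmarkFixture()
#' idx <- loadOntology(fx$path)
#' categorizePair(idx, fx$expected$tool_iri[1], fx$expected$benchmark_iri[1])
#' @export
categorizePair <- function(index, tIri, hIri) {
  if (is.null(index@terms[[tIri]])) omStop("unknown term IRI: ", tIri)
  if (is.null(index@terms[[hIri]])) omStop("unknown term IRI: ", hIri)
  if (tIri == hIri) return("Same")
  if (hIri %in% ancestors(index, tIri)) return("MoreSpecific")
  if (tIri %in% ancestors(index, hIri)) return("MoreGeneral")
  if (length(intersect(index@terms[[tIri]]$parents,
                       index@terms[[hIri]]$parents))) {
    return("Sibling")
  }
  "Unrelated"
}

#' Compare tool mappings against a benchmark mapping set
#'
#' For each benchmark entry, the tool's top-ranked mapping for the same
#' input text is categorized against the benchmark term with
#' [categorizePair()], and categories are aggregated into counts and
#' percentages. Inputs the tool left unmapped are counted separately (not
#' as Unrelated), as are entries whose IRIs cannot be resolved in the
#' index. Benchmark entries pointing at deprecated terms are retained and
#' flagged in the per-pair table.
#'
#' @param tool a [MappingTable-class] with the tool's mappings.
#' @param benchmark `data.frame` with columns `input_text`, `iri`
#'   (typically from [filterUnambiguous()]).
#' @param index the [OntologyIndex-class] both mapping sets refer to.
#' @return a [ComparisonReport-class].
#' @examples
#' fx <- diseaseBenchmarkFixture()
#' idx <- loadOntology(fx$path)
#' tab <- mapTerms(fx$expected$input_text, idx)
#' benchmark <- data.frame(input_text = fx$expected$input_text,
#'                         iri = fx$expected$benchmark_iri)
#' compareMappingSets(tab, benchmark, idx)
#' @export
compareMappingSets <- function(tool, benchmark, index) {
  rows <- tool@rows
  top <- rows[!duplicated(rows$source_term), , drop = FALSE]
  excluded <- c(ambiguous = attr(benchmark, "excluded_ambiguous") %||% 0L,
                unresolvable = 0L, unmapped = 0L)
  n <- nrow(benchmark)
  input_text <- character(n); t_iri <- character(n); h_iri <- character(n)
  category <- character(n); h_dep <- logical(n)
  k <- 0L
  for (i in seq_len(n)) {
    input <- benchmark$input_text[i]
    h <- benchmark$iri[i]
    hit <- match(input, top$source_term)
    if (is.na(hit)) {
      excluded[["unmapped"]] <- excluded[["unmapped"]] + 1L
      next
    }
    t <- top$term_iri[hit]
    if (is.null(index@terms[[t]]) || is.null(index@terms[[h]])) {
      excluded[["unresolvable"]] <- excluded[["unresolvable"]] + 1L
      next
    }
    k <- k + 1L
    input_text[k] <- input; t_iri[k] <- t; h_iri[k] <- h
    category[k] <- categorizePair(index, t, h)
    h_dep[k] <- index@terms[[h]]$deprecated
  }
  pairs <- data.frame(input_text = input_text[seq_len(k)],
                      tool_iri = t_iri[seq_len(k)],
                      benchmark_iri = h_iri[seq_len(k)],
                      category = category[seq_len(k)],
                      benchmark_deprecated = h_dep[seq_len(k)],
                      stringsAsFactors = FALSE)
  counts <- vapply(.CATEGORIES, function(cat) sum(pairs$category == cat),
                   integer(1))
  percents <- if (k > 0) 100 * counts / k else counts * 0
  new("ComparisonReport", counts = counts,
      percents = stats::setNames(as.numeric(percents), .CATEGORIES),
      pairs = pairs, excluded = vapply(excluded, as.integer, integer(1)))
}

#' Read a benchmark mapping set
#'
#' Accepts either an SSSOM-style TSV (columns `subject_id`,
#' `subject_label`, `object_id`, ...) — the subject label becomes the input
#' text and the object the benchmark term — or a two-column delimited file
#' `input_text, iri`.
#'
#' @param path benchmark file.
#' @return `data.frame` with columns `input_text`, `iri`.
#' @export
readBenchmark <- function(path) {
  if (!file.exists(path)) omStop("cannot read benchmark file: ", path)
  sep <- if (grepl("\\.tsv$|\\.sssom(\\.tsv)?$", path)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "#")
  if (all(c("subject_id", "object_id") %in% names(tab))) {
    input <- if ("subject_label" %in% names(tab)) tab$subject_label
             else tab$subject_id
    return(data.frame(input_text = input, iri = tab$object_id,
                      stringsAsFactors = FALSE))
  }
  if (all(c("input_text", "iri") %in% names(tab))) {
    return(tab[c("input_text", "iri")])
  }
  if (ncol(tab) >= 2) {
    return(stats::setNames(tab[1:2], c("input_text", "iri")))
  }
  omStop("unrecognized benchmark schema in ", path,
         "; detected columns: ", paste(names(tab), collapse = ", "))
}

#' Write a comparison report
#'
#' Writes the per-pair categories as CSV, preceded by `#` header lines with
#' the aggregate counts and percentages and the excluded-entry tallies.
#'
#' @param report a [ComparisonReport-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeComparisonReport <- function(report, path) {
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) omStop("cannot write to ", path))
  on.exit(close(con))
  for (cat_name in names(report@counts)) {
    writeLines(sprintf("# %s: %d (%.1f%%)", cat_name,
                       report@counts[[cat_name]],
                       report@percents[[match(cat_name,
                                              names(report@counts))]]), con)
  }
  for (ex in names(report@excluded)) {
    writeLines(sprintf("# excluded_%s: %d", ex, report@excluded[[ex]]), con)
  }
  utils::write.table(report@pairs, con, sep = ",", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}
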