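# TF-IDF character n-gram mapper.
#
# Every string (ontology name or query) becomes a document over character
# n-grams of the normalized string padded with one leading and one trailing
# space; documents are TF-IDF weighted (smooth IDF) and length-normalized,
# so cosine similarity is a sparse matrix product. Padding makes word
# boundaries part of the token stream and guarantees that any non-empty
# string has at least one trigram.

#' Character n-grams of a padded string
#'
#' @param text character vector (already normalized).
#' @param n n-gram length.
#' @return list of character vectors, one per input string; an element is
#'   empty when the padded string is shorter than `n`.
#' @examples
#' charNgrams("flu", 3)
#' @export
charNgrams <- function(text, n = 3L) {
  n <- as.integer(n)
  padded <- ifelse(nzchar(text), paste0(" ", text, " "), "")
  lapply(padded, function(p) {
    len <- nchar(p)
    if (len < n) return(character())
    substring(p, seq_len(len - n + 1L), seq_len(len - n + 1L) + n - 1L)
  })
}

# Sparse row-l2-normalized TF-IDF matrix for a list of token vectors, given
# a fixed vocabulary and IDF weights.
tfidfMatrix <- function(grams, vocab, idf) {
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (d in seq_along(grams)) {
    tok <- grams[[d]]
    if (!length(tok)) next
    idx <- match(tok, vocab)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) next
    tab <- table(idx)
    j <- as.integer(names(tab))
    w <- as.numeric(tab) * idf[j]
    norm <- sqrt(sum(w^2))
    if (norm == 0) next
    ii <- c(ii, rep(d, length(j))); jj <- c(jj, j); xx <- c(xx, w / norm)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(grams), length(vocab)))
}

# Smooth IDF over the fitting documents: log((1 + N) / (1 + df)) + 1.
computeIdf <- function(grams, vocab) {
  df <- numeric(length(vocab))
  for (tok in grams) {
    idx <- unique(match(tok, vocab))
    idx <- idx[!is.na(idx)]
    df[idx] <- df[idx] + 1
  }
  log((1 + length(grams)) / (1 + df)) + 1
}

# Shared post-processing for all batch mappers: collapse scores to the best
# name per term, rank by descending score with ties broken by term IRI,
# filter at minScore, truncate to maxMappings.
rankMatches <- function(source_index, term_iri, matched_name, name_kind,
                        score, config) {
  # a zero similarity means no overlap at all and is never a match, even
  # at minScore = 0
  keep <- score >= config@minScore & score > 0
  df <- data.frame(source_index = source_index[keep],
                   term_iri = term_iri[keep],
                   matched_name = matched_name[keep],
                   name_kind = name_kind[keep],
                   score = pmin(score[keep], 1), stringsAsFactors = FALSE)
  if (!nrow(df)) return(df)
  # best name per (source, term); ties on score keep the earliest corpus name
  df <- df[order(df$source_index, df$term_iri, -df$score), , drop = FALSE]
  df <- df[!duplicated(df[c("source_index", "term_iri")]), , drop = FALSE]
  # rank within source: score desc, then IRI ascending for reproducibility
  df <- df[order(df$source_index, -df$score, df$term_iri), , drop = FALSE]
  rank_in_src <- stats::ave(seq_len(nrow(df)), df$source_index,
                            FUN = seq_along)
  df <- df[rank_in_src <= config@maxMappings, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Map source terms with the TF-IDF mapper
#'
#' Vectorizes queries and ontology names by TF-IDF over character n-grams
#' and scores every (query, name) pair by cosine similarity, computed as a
#' sparse matrix product over the whole batch. Per source term, scores are
#' collapsed to the best name per ontology term, ranked by descending score
#' (ties broken by term IRI), filtered at `minScore` and truncated to
#' `maxMappings`.
#'
#' By default the IDF is fitted on the union of ontology names and the query
#' batch so both sides share one vocabulary; note that scores can then shift
#' slightly across query batches. Set `fitCorpusOnly = TRUE` in the config
#' to fit on the ontology names alone.
#'
#' A source term whose normalized text yields no n-grams produces no
#' matches; it is reported as unmapped by [mapTerms()], not as an error.
#'
#' @param sources character vector of source terms, or a data.frame with a
#'   `text` column.
#' @param corpus name corpus from [buildNameCorpus()].
#' @param config a [MapperConfig-class].
#' @return `data.frame` of raw matches with columns `source_index`,
#'   `term_iri`, `matched_name`, `name_kind`, `score`.
#' @examples
#' fx <- generateToyOntology(nTerms = 10, seed = 7)
#' idx <- loadOntology(fx$path)
#' corpus <- buildNameCorpus(idx)
#' tfidfMap(fx$groundTruth$terms$label[1], corpus)
#' @export
tfidfMap <- function(sources, corpus, config = mapperConfig("tfidf")) {
  sources <- asSourceTerms(sources)
  if (!nrow(corpus)) omStop("no matchable names")
  queries <- normalizeText(sources$text)
  qgrams <- charNgrams(queries, config@ngramSize)
  cgrams <- charNgrams(corpus$name, config@ngramSize)
  fit_grams <- if (config@fitCorpusOnly) cgrams else c(cgrams, qgrams)
  vocab <- sort(unique(unlist(fit_grams, use.names = FALSE)))
  if (!length(vocab)) {
    return(rankMatches(integer(), character(), character(), character(),
                       numeric(), config))
  }
  idf <- computeIdf(fit_grams, vocab)
  D <- tfidfMatrix(cgrams, vocab, idf)
  Q <- tfidfMatrix(qgrams, vocab, idf)
  S <- Q %*% Matrix::t(D)           # queries x names cosine similarities
  S <- as(S, "TsparseMatrix")
  rankMatches(source_index = S@i + 1L,
              term_iri = corpus$term_iri[S@j + 1L],
              matched_name = corpus$name[S@j + 1L],
              name_kind = corpus$name_kind[S@j + 1L],
              score = S@x,
              config = config)
}
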