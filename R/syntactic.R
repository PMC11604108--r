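# Syntactic (edit-distance) similarity metrics, each normalized to [0, 1]
# with 1 meaning identical strings:
#   levenshtein: 1 - dist / max(|a|, |b|)
#   indel:       1 - dist / (|a| + |b|), insertions/deletions only
#   jaro, jarowinkler: standard definitions (Winkler prefix scale 0.1,
#                      prefix capped at 4)
#   jaccard:     |A n B| / |A u B| over padded character 3-gram sets
# Levenshtein and indel distances come from utils::adist (indel = unit
# insertion/deletion with substitution cost 2); Jaro and Jaro-Winkler are
# implemented here.

jaroSim <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la == 0L && lb == 0L) return(1)
  if (la == 0L || lb == 0L) return(0)
  if (a == b) return(1)
  sa <- strsplit(a, "", fixed = TRUE)[[1]]
  sb <- strsplit(b, "", fixed = TRUE)[[1]]
  window <- max(0L, max(la, lb) %/% 2L - 1L)
  matched_a <- logical(la); matched_b <- logical(lb)
  for (i in seq_len(la)) {
    lo <- max(1L, i - window); hi <- min(lb, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!matched_b[j] && sa[i] == sb[j]) {
        matched_a[i] <- TRUE; matched_b[j] <- TRUE
        break
      }
    }
  }
  m <- sum(matched_a)
  if (m == 0L) return(0)
  transpositions <- sum(sa[matched_a] != sb[matched_b]) / 2
  (m / la + m / lb + (m - transpositions) / m) / 3
}

jaroWinklerSim <- function(a, b, prefix_scale = 0.1, max_prefix = 4L) {
  j <- jaroSim(a, b)
  shared <- 0L
  upto <- min(nchar(a), nchar(b), max_prefix)
  while (shared < upto &&
         substr(a, shared + 1L, shared + 1L) ==
           substr(b, shared + 1L, shared + 1L)) {
    shared <- shared + 1L
  }
  j + shared * prefix_scale * (1 - j)
}

jaccardSim <- function(a, b, ngramSize = 3L) {
  if (!nzchar(a) && !nzchar(b)) return(1)
  if (!nzchar(a) || !nzchar(b)) return(0)
  ga <- unique(charNgrams(a, ngramSize)[[1]])
  gb <- unique(charNgrams(b, ngramSize)[[1]])
  if (!length(ga) && !length(gb)) return(1)
  length(intersect(ga, gb)) / length(union(ga, gb))
}

#' Normalized syntactic similarity between two strings
#'
#' Inputs are expected to be normalized (see [normalizeText()]). Two empty
#' strings have similarity 1 by convention; one empty string gives 0.
#'
#' @param metric one of `"levenshtein"`, `"jaro"`, `"jarowinkler"`,
#'   `"jaccard"`, `"indel"`.
#' @param a,b strings to compare.
#' @param ngramSize gram length for the Jaccard metric (default 3).
#' @return similarity in `[0, 1]`; 1 means identical.
#' @examples
#' syntacticSimilarity("levenshtein", "kitten", "sitting")  # 1 - 3/7
#' syntacticSimilarity("jaro", "abc", "abc")
#' @export
syntacticSimilarity <- function(metric, a, b, ngramSize = 3L) {
  metric <- match.arg(metric, .SYNTACTIC_METRICS)
  a <- as.character(a); b <- as.character(b)
  la <- nchar(a); lb <- nchar(b)
  if (la == 0L && lb == 0L) return(1)
  if (la == 0L || lb == 0L) return(0)
  switch(metric,
    levenshtein = 1 - drop(utils::adist(a, b)) / max(la, lb),
    indel = {
      d <- drop(utils::adist(a, b, costs = list(insertions = 1,
                                                deletions = 1,
                                                substitutions = 2)))
      1 - d / (la + lb)
    },
    jaro = jaroSim(a, b),
    jarowinkler = jaroWinklerSim(a, b),
    jaccard = jaccardSim(a, b, ngramSize))
}

#' Map source terms with a syntactic distance mapper
#'
#' Compares each source term pairwise against every ontology name in the
#' corpus; the score of a (source, term) pair is the maximum similarity over
#' the term's names. Ranking, tie-breaking, score filtering and truncation
#' follow the same contract as [tfidfMap()].
#'
#' @inheritParams tfidfMap
#' @param config a [MapperConfig-class] whose `mapper` names one of the five
#'   syntactic metrics.
#' @return `data.frame` of raw matches (see [tfidfMap()]).
#' @examples
#' fx <- generateToyOntology(nTerms = 10, seed = 7)
#' corpus <- buildNameCorpus(loadOntology(fx$path))
#' syntacticMap(fx$groundTruth$terms$label[1], corpus,
#'              mapperConfig("levenshtein"))
#' @export
syntacticMap <- function(sources, corpus, config) {
  sources <- asSourceTerms(sources)
  metric <- match.arg(config@mapper, .SYNTACTIC_METRICS)
  if (!nrow(corpus)) omStop("no matchable names")
  queries <- normalizeText(sources$text)
  if (metric %in% c("levenshtein", "indel")) {
    # adist computes the full query x name distance matrix in C
    costs <- if (metric == "indel")
      list(insertions = 1, deletions = 1, substitutions = 2) else NULL
    dmat <- utils::adist(queries, corpus$name, costs = costs)
    lq <- nchar(queries); ln <- nchar(corpus$name)
    denom <- if (metric == "indel") outer(lq, ln, `+`)
             else outer(lq, ln, pmax)
    smat <- 1 - dmat / pmax(denom, 1L)
    smat[lq == 0L, ] <- 0
  } else {
    smat <- matrix(0, nrow = length(queries), ncol = nrow(corpus))
    for (q in seq_along(queries)) {
      for (d in seq_len(nrow(corpus))) {
        smat[q, d] <- switch(metric,
          jaro = jaroSim(queries[q], corpus$name[d]),
          jarowinkler = jaroWinklerSim(queries[q], corpus$name[d]),
          jaccard = jaccardSim(queries[q], corpus$name[d], config@ngramSize))
      }
    }
    smat[!nzchar(queries), ] <- 0
  }
  idx <- which(smat >= config@minScore, arr.ind = TRUE)
  rankMatches(source_index = idx[, 1L],
              term_iri = corpus$term_iri[idx[, 2L]],
              matched_name = corpus$name[idx[, 2L]],
              name_kind = corpus$name_kind[idx[, 2L]],
              score = smat[idx],
              config = config)
}
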