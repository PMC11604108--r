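# Independent oracle implementations used to check the package's mappers
# and hierarchy logic. These deliberately share no code with the package:
# dense loops and recursive graph walks instead of sparse matrices and
# memoized fixpoints.

# --- string-distance oracles ---------------------------------------------

# Classic dynamic-programming edit distance.
dpLevenshtein <- function(a, b) {
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  la <- length(sa); lb <- length(sb)
  d <- matrix(0L, la + 1L, lb + 1L)
  d[, 1L] <- 0:la; d[1L, ] <- 0:lb
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      cost <- if (sa[i] == sb[j]) 0L else 1L
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                               d[i, j] + cost)
    }
  }
  d[la + 1L, lb + 1L]
}

# Indel distance via the longest common subsequence: |a| + |b| - 2 LCS.
dpIndel <- function(a, b) {
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  la <- length(sa); lb <- length(sb)
  l <- matrix(0L, la + 1L, lb + 1L)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      l[i + 1L, j + 1L] <- if (sa[i] == sb[j]) l[i, j] + 1L
                           else max(l[i, j + 1L], l[i + 1L, j])
    }
  }
  la + lb - 2L * l[la + 1L, lb + 1L]
}

# Jaro similarity written as a direct transcription of the definition,
# using explicit per-character match bookkeeping over the other string.
oracleJaro <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la == 0 && lb == 0) return(1)
  if (la == 0 || lb == 0) return(0)
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  w <- max(0, floor(max(la, lb) / 2) - 1)
  used_b <- rep(FALSE, lb)
  a_matches <- character(); b_positions <- integer()
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      if (!used_b[j] && abs(i - j) <= w && sa[i] == sb[j]) {
        used_b[j] <- TRUE
        a_matches <- c(a_matches, sa[i])
        b_positions <- c(b_positions, j)
        break
      }
    }
  }
  m <- length(a_matches)
  if (m == 0) return(0)
  b_matches <- sb[sort(b_positions)]
  t <- sum(a_matches != b_matches) / 2
  mean(c(m / la, m / lb, (m - t) / m))
}

oracleJaroWinkler <- function(a, b) {
  j <- oracleJaro(a, b)
  prefix <- 0
  for (k in seq_len(min(4, nchar(a), nchar(b)))) {
    if (substr(a, k, k) == substr(b, k, k)) prefix <- prefix + 1 else break
  }
  j + 0.1 * prefix * (1 - j)
}

# Jaccard over padded character n-gram sets built by explicit substring
# enumeration.
oracleGramSet <- function(x, n = 3) {
  if (!nzchar(x)) return(character())
  p <- paste0(" ", x, " ")
  grams <- character()
  for (i in seq_len(nchar(p) - n + 1)) {
    grams <- c(grams, substr(p, i, i + n - 1))
  }
  unique(grams)
}

oracleJaccard <- function(a, b, n = 3) {
  if (!nzchar(a) && !nzchar(b)) return(1)
  if (!nzchar(a) || !nzchar(b)) return(0)
  A <- oracleGramSet(a, n); B <- oracleGramSet(b, n)
  length(intersect(A, B)) / length(union(A, B))
}

oracleSimilarity <- function(metric, a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la == 0 && lb == 0) return(1)
  if (la == 0 || lb == 0) return(0)
  switch(metric,
         levenshtein = 1 - dpLevenshtein(a, b) / max(la, lb),
         indel = 1 - dpIndel(a, b) / (la + lb),
         jaro = oracleJaro(a, b),
         jarowinkler = oracleJaroWinkler(a, b),
         jaccard = oracleJaccard(a, b))
}

# --- dense TF-IDF oracle --------------------------------------------------

# Brute-force TF-IDF + cosine over all (query, name) pairs with dense named
# vectors, followed by the same ranking contract (best name per term,
# score-then-IRI order, min-score filter, truncation).
denseTfidfOracle <- function(queries, corpus, ngram = 3, maxMappings = 3,
                             minScore = 0.3, fitCorpusOnly = FALSE) {
  grams <- function(x) {
    if (!nzchar(x)) return(character())
    p <- paste0(" ", x, " ")
    if (nchar(p) < ngram) return(character())
    vapply(seq_len(nchar(p) - ngram + 1),
           function(i) substr(p, i, i + ngram - 1), character(1))
  }
  qn <- tolower(trimws(gsub("\\s+", " ", queries)))
  qg <- lapply(qn, grams)
  cg <- lapply(corpus$name, grams)
  fitted <- if (fitCorpusOnly) cg else c(cg, qg)
  vocab <- sort(unique(unlist(fitted)))
  df <- sapply(vocab, function(v) {
    sum(vapply(fitted, function(g) v %in% g, logical(1)))
  })
  idf <- log((1 + length(fitted)) / (1 + df)) + 1
  names(idf) <- vocab
  vec <- function(g) {
    v <- rep(0, length(vocab)); names(v) <- vocab
    for (tok in g) if (tok %in% vocab) v[tok] <- v[tok] + 1
    v <- v * idf
    norm <- sqrt(sum(v^2))
    if (norm > 0) v / norm else v
  }
  cvecs <- lapply(cg, vec)
  out <- list()
  for (q in seq_along(qg)) {
    qv <- vec(qg[[q]])
    scores <- vapply(cvecs, function(cv) sum(qv * cv), numeric(1))
    per_term <- tapply(scores, corpus$term_iri, max)
    cand <- data.frame(term_iri = names(per_term),
                       score = as.numeric(per_term),
                       stringsAsFactors = FALSE)
    cand <- cand[cand$score >= minScore & cand$score > 0, , drop = FALSE]
    cand <- cand[order(-cand$score, cand$term_iri), , drop = FALSE]
    cand <- head(cand, maxMappings)
    if (nrow(cand)) {
      cand$source_index <- q
      out[[length(out) + 1L]] <- cand
    }
  }
  if (!length(out)) {
    return(data.frame(source_index = integer(), term_iri = character(),
                      score = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("source_index", "term_iri", "score")]
}

# --- hierarchy oracles ----------------------------------------------------

# Recursive depth-first ancestor search over a parent-list representation.
dfsAncestors <- function(parent_map, iri) {
  seen <- character()
  visit <- function(x) {
    for (p in parent_map[[x]]) {
      if (!p %in% seen) {
        seen <<- c(seen, p)
        if (!is.null(parent_map[[p]])) visit(p)
      }
    }
  }
  visit(iri)
  sort(unique(seen))
}

# Brute-force categorization against the DFS closure oracle.
oracleCategorize <- function(parent_map, t, h) {
  if (t == h) return("Same")
  if (h %in% dfsAncestors(parent_map, t)) return("MoreSpecific")
  if (t %in% dfsAncestors(parent_map, h)) return("MoreGeneral")
  if (length(intersect(parent_map[[t]], parent_map[[h]]))) return("Sibling")
  "Unrelated"
}

parentMapFromIndex <- function(index) {
  iris <- termIRIs(index)
  pm <- lapply(iris, function(i) getTerm(index, i)$parents)
  names(pm) <- iris
  pm
}
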