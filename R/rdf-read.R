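# Triple extraction from OWL documents.
#
# Both readers produce the same flat triple table:
#   subject, predicate, object (character), literal (logical)
# Blank nodes get "_:bN" identifiers so the index builder can count and skip
# anonymous classes (e.g. owl:Restriction) in parent position.

RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"
XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"
SKOS_NS <- "http://www.w3.org/2004/02/skos/core#"
OBOINOWL_NS <- "http://www.geneontology.org/formats/oboInOwl#"

IRI_TYPE <- paste0(RDF_NS, "type")
IRI_SUBCLASS <- paste0(RDFS_NS, "subClassOf")
IRI_SUBPROP <- paste0(RDFS_NS, "subPropertyOf")
IRI_LABEL <- paste0(RDFS_NS, "label")
IRI_PREFLABEL <- paste0(SKOS_NS, "prefLabel")
IRI_EXACT_SYN <- paste0(OBOINOWL_NS, "hasExactSynonym")
IRI_BROAD_SYN <- paste0(OBOINOWL_NS, "hasBroadSynonym")
IRI_NCIT_SYN <- "http://ncicb.nci.nih.gov/xml/owl/EVS/Thesaurus.owl#P90"
IRI_EFO_SYN <- "http://www.ebi.ac.uk/efo/alternative_term"
IRI_SKOS_DEF <- paste0(SKOS_NS, "definition")
IRI_IAO_DEF <- "http://purl.obolibrary.org/obo/IAO_0000115"
IRI_DEPRECATED <- paste0(OWL_NS, "deprecated")
IRI_OBSOLETE_CLASS <- paste0(OBOINOWL_NS, "ObsoleteClass")
IRI_OWL_CLASS <- paste0(OWL_NS, "Class")
IRI_OWL_ONTOLOGY <- paste0(OWL_NS, "Ontology")
IRI_OWL_NAMED_INDIVIDUAL <- paste0(OWL_NS, "NamedIndividual")
IRI_VERSION_INFO <- paste0(OWL_NS, "versionInfo")
IRI_VERSION_IRI <- paste0(OWL_NS, "versionIRI")
IRI_PROPERTY_TYPES <- c(paste0(OWL_NS, c("ObjectProperty", "DatatypeProperty",
                                         "AnnotationProperty")),
                        paste0(RDF_NS, "Property"))

newTripleSink <- function() {
  env <- new.env(parent = emptyenv())
  env$s <- character(); env$p <- character(); env$o <- character()
  env$lit <- logical(); env$n <- 0L; env$bnodes <- 0L
  env
}

addTriple <- function(sink, s, p, o, lit) {
  sink$n <- sink$n + 1L
  sink$s[sink$n] <- s; sink$p[sink$n] <- p
  sink$o[sink$n] <- o; sink$lit[sink$n] <- lit
}

sinkToFrame <- function(sink) {
  data.frame(subject = sink$s[seq_len(sink$n)],
             predicate = sink$p[seq_len(sink$n)],
             object = sink$o[seq_len(sink$n)],
             literal = sink$lit[seq_len(sink$n)],
             stringsAsFactors = FALSE)
}

#' Read an OWL document into a triple table
#'
#' Dispatches between RDF/XML and Turtle on content sniffing (an XML
#' declaration or `<rdf:RDF` root means RDF/XML).
#'
#' @param path local file path.
#' @return list with `triples` (data.frame) and `blank_nodes` (count).
#' @noRd
readTriples <- function(path) {
  head_txt <- readChar(path, nchars = 4096L, useBytes = TRUE)
  if (grepl("^\\s*<\\?xml", head_txt) || grepl("<rdf:RDF", head_txt, fixed = TRUE) ||
      grepl("^\\s*<", head_txt) && !grepl("@prefix", head_txt, fixed = TRUE)) {
    readRdfXml(path)
  } else {
    readTurtle(path)
  }
}

## ---- RDF/XML -------------------------------------------------------------

readRdfXml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    omStop("cannot parse RDF/XML document ", path, ": ",
                           conditionMessage(e))
                  })
  ns <- xml2::xml_ns(doc)
  expand <- function(qname) {
    colon <- regexpr(":", qname, fixed = TRUE)
    if (colon > 0) {
      prefix <- substr(qname, 1, colon - 1)
      if (prefix %in% names(ns)) {
        return(paste0(ns[[prefix]], substring(qname, colon + 1)))
      }
    }
    qname
  }
  rdf_prefix <- names(ns)[ns == RDF_NS]
  if (!length(rdf_prefix)) omStop(path, " is not an RDF/XML document")
  aboutAttr <- paste0(rdf_prefix[1], ":about")
  resourceAttr <- paste0(rdf_prefix[1], ":resource")
  idAttr <- paste0(rdf_prefix[1], ":ID")

  sink <- newTripleSink()

  # Walks one node element, emitting its type and property triples, and
  # returns its subject identifier (IRI or fresh blank-node id).
  getAttr <- function(attrs, name) {
    if (name %in% names(attrs)) unname(attrs[[name]]) else NULL
  }

  walkNode <- function(node) {
    attrs <- xml2::xml_attrs(node, ns)
    subj <- getAttr(attrs, aboutAttr) %||% getAttr(attrs, idAttr)
    if (is.null(subj)) {
      sink$bnodes <- sink$bnodes + 1L
      subj <- paste0("_:b", sink$bnodes)
    }
    name <- expand(xml2::xml_name(node, ns))
    if (name != paste0(RDF_NS, "Description")) {
      addTriple(sink, subj, IRI_TYPE, name, FALSE)
    }
    for (child in xml2::xml_children(node)) {
      pred <- expand(xml2::xml_name(child, ns))
      cattrs <- xml2::xml_attrs(child, ns)
      res <- getAttr(cattrs, resourceAttr)
      if (!is.null(res)) {
        addTriple(sink, subj, pred, res, FALSE)
      } else if (length(xml2::xml_children(child))) {
        for (grand in xml2::xml_children(child)) {
          addTriple(sink, subj, pred, walkNode(grand), FALSE)
        }
      } else {
        addTriple(sink, subj, pred, xml2::xml_text(child, trim = TRUE), TRUE)
      }
    }
    subj
  }

  for (top in xml2::xml_children(doc)) walkNode(top)
  list(triples = sinkToFrame(sink), blank_nodes = sink$bnodes)
}

## ---- Turtle --------------------------------------------------------------

# A constrained Turtle reader: @prefix/PREFIX declarations, IRIs, prefixed
# names, string literals with \-escapes plus optional @lang or ^^datatype,
# booleans/numbers, the 'a' keyword, ';' and ',' continuations, and
# anonymous bnode property lists '[ ... ]'. Collections '( )' and multi-line
# """strings""" are not supported; biomedical OWL exports in Turtle stay
# within this subset.

turtleTokens <- function(text) {
  tokens <- character(); kinds <- character()
  i <- 1L; n <- nchar(text)
  push <- function(tok, kind) {
    tokens[[length(tokens) + 1L]] <<- tok
    kinds[[length(kinds) + 1L]] <<- kind
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch %in% c(" ", "\t", "\r", "\n")) { i <- i + 1L; next }
    if (ch == "#") {  # comment to end of line
      nl <- regexpr("\n", substr(text, i, n), fixed = TRUE)
      i <- if (nl > 0) i + nl else n + 1L
      next
    }
    if (ch == "<") {
      close <- regexpr(">", substr(text, i, n), fixed = TRUE)
      if (close < 0) omStop("unterminated IRI in Turtle document")
      push(substr(text, i + 1L, i + close - 2L), "iri")
      i <- i + close
      next
    }
    if (ch == "\"") {
      j <- i + 1L
      out <- character()
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\") {
          esc <- substr(text, j + 1L, j + 1L)
          out[[length(out) + 1L]] <- switch(esc,
            n = "\n", t = "\t", r = "\r", "\"" = "\"", "\\" = "\\", esc)
          j <- j + 2L
        } else if (cj == "\"") break
        else { out[[length(out) + 1L]] <- cj; j <- j + 1L }
      }
      if (j > n) omStop("unterminated string literal in Turtle document")
      push(paste0(out, collapse = ""), "string")
      i <- j + 1L
      # optional @lang or ^^datatype suffix: consume, it does not affect
      # the extracted value
      rest <- substr(text, i, n)
      m <- regexpr("^@[A-Za-z][A-Za-z0-9-]*", rest)
      if (m > 0) i <- i + attr(m, "match.length")
      rest <- substr(text, i, n)
      if (startsWith(rest, "^^")) {
        i <- i + 2L
        rest <- substr(text, i, n)
        if (startsWith(rest, "<")) {
          close <- regexpr(">", rest, fixed = TRUE)
          i <- i + close
        } else {
          m <- regexpr("^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]*", rest)
          if (m > 0) i <- i + attr(m, "match.length")
        }
      }
      next
    }
    if (ch %in% c(".", ";", ",", "[", "]")) {
      push(ch, "punct"); i <- i + 1L; next
    }
    rest <- substr(text, i, n)
    m <- regexpr("^@?[A-Za-z][A-Za-z0-9_-]*", rest)
    if (m > 0 && substr(rest, attr(m, "match.length") + 1L,
                        attr(m, "match.length") + 1L) != ":") {
      word <- substr(rest, 1L, attr(m, "match.length"))
      kind <- if (word %in% c("@prefix", "@base", "a", "true", "false"))
        "keyword" else "word"
      push(word, kind)
      i <- i + attr(m, "match.length")
      next
    }
    m <- regexpr("^[A-Za-z0-9_.-]*:[A-Za-z0-9_.%-]*", rest)
    if (m > 0) {
      push(substr(rest, 1L, attr(m, "match.length")), "pname")
      i <- i + attr(m, "match.length")
      next
    }
    m <- regexpr("^[+-]?[0-9][0-9.eE+-]*", rest)
    if (m > 0) {
      push(substr(rest, 1L, attr(m, "match.length")), "number")
      i <- i + attr(m, "match.length")
      next
    }
    omStop("unexpected character '", ch, "' in Turtle document")
  }
  data.frame(token = tokens, kind = kinds, stringsAsFactors = FALSE)
}

readTurtle <- function(path) {
  text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                collapse = "\n")
  toks <- turtleTokens(text)
  prefixes <- character()
  sink <- newTripleSink()
  i <- 1L
  ntok <- nrow(toks)
  peek <- function() if (i <= ntok) toks$token[i] else NA_character_
  peekKind <- function() if (i <= ntok) toks$kind[i] else NA_character_
  advance <- function() { tok <- toks$token[i]; i <<- i + 1L; tok }
  expect <- function(tok) {
    got <- advance()
    if (!identical(got, tok)) {
      omStop("malformed Turtle: expected '", tok, "' but found '", got, "'")
    }
  }
  resolvePname <- function(pname) {
    colon <- regexpr(":", pname, fixed = TRUE)
    prefix <- substr(pname, 1L, colon - 1L)
    local <- substring(pname, colon + 1L)
    if (!prefix %in% names(prefixes)) {
      omStop("undeclared Turtle prefix '", prefix, ":'")
    }
    paste0(prefixes[[prefix]], local)
  }
  parseTermOrLiteral <- function() {
    kind <- peekKind()
    tok <- advance()
    if (kind == "iri") return(list(value = tok, literal = FALSE))
    if (kind == "pname") return(list(value = resolvePname(tok),
                                     literal = FALSE))
    if (kind == "string" || kind == "number") {
      return(list(value = tok, literal = TRUE))
    }
    if (tok %in% c("true", "false")) return(list(value = tok, literal = TRUE))
    if (tok == "[") {
      sink$bnodes <- sink$bnodes + 1L
      bnode <- paste0("_:b", sink$bnodes)
      if (!identical(peek(), "]")) parsePredicateList(bnode)
      expect("]")
      return(list(value = bnode, literal = FALSE))
    }
    omStop("malformed Turtle: unexpected token '", tok, "'")
  }
  parsePredicateList <- function(subj) {
    repeat {
      ptok <- advance()
      pred <- if (identical(ptok, "a")) IRI_TYPE
              else if (toks$kind[i - 1L] == "iri") ptok
              else resolvePname(ptok)
      repeat {
        obj <- parseTermOrLiteral()
        addTriple(sink, subj, pred, obj$value, obj$literal)
        if (identical(peek(), ",")) advance() else break
      }
      if (identical(peek(), ";")) {
        advance()
        # tolerate trailing ';' before '.' or ']'
        if (identical(peek(), ".") || identical(peek(), "]")) break
      } else break
    }
  }
  while (i <= ntok) {
    tok <- peek()
    if (identical(tok, "@prefix") || identical(toupper(tok), "PREFIX")) {
      advance()
      pname <- advance()                      # e.g. "efo:" or ":"
      prefix <- sub(":$", "", pname)
      iri_tok <- advance()
      prefixes[[prefix]] <- iri_tok
      if (identical(peek(), ".")) advance()
      next
    }
    if (identical(tok, "@base")) {
      advance(); advance()
      if (identical(peek(), ".")) advance()
      next
    }
    subj_term <- parseTermOrLiteral()
    if (subj_term$literal) omStop("malformed Turtle: literal subject")
    parsePredicateList(subj_term$value)
    expect(".")
  }
  list(triples = sinkToFrame(sink), blank_nodes = sink$bnodes)
}
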