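## TriG / N-Quads serialization and parsing.
##
## TriG is the normative format: the default graph carries the
## assertion/provenance structure and every proposition is a named graph.
## N-Quads is offered as a second dialect. The writer is deterministic:
## prefixes, graphs and triples are emitted in sorted order and blank
## nodes are relabelled canonically per graph (structural-signature
## order), so re-serializing a parsed document is byte-stable.
##
## Supported TriG subset on input: prefix directives (@prefix/PREFIX),
## graph blocks with optional GRAPH keyword, predicate-object (';') and
## object (',') lists, 'a', IRIs, prefixed names, blank node labels,
## string literals (short/long, single/double quoted) with language tags
## or datatypes, and bare integer/decimal/boolean abbreviations. Blank
## node labels are scoped per graph; anonymous '[]' nodes and
## collections are not accepted.

## ---- blank-node signatures ------------------------------------------

## Iterated structural refinement: each blank node's signature summarizes
## the predicates and (ground or signature-typed) neighbours around it.
## Used for canonical output order and as a pruning key for isomorphism.
bnodeSignatures <- function(tr) {
  bs <- tr$s[isBlank(tr$s)]
  bo <- tr$o[tr$o_kind == "bnode"]
  bn <- unique(c(bs, bo))
  if (!length(bn)) return(stats::setNames(character(0), character(0)))
  sig <- stats::setNames(rep("b", length(bn)), bn)
  groundKey <- function(i) {
    o <- tr$o[i]
    paste(tr$o_kind[i], o, tr$o_lang[i], tr$o_dt[i], sep = "\r")
  }
  for (iter in seq_len(length(bn) + 1L)) {
    new <- sig
    for (b in bn) {
      out <- which(tr$s == b)
      toks <- character(0)
      if (length(out)) {
        ok <- tr$o_kind[out] == "bnode"
        toks <- c(toks,
                  paste0("O|", tr$p[out],
                         "|", ifelse(ok, paste0("B<", sig[tr$o[out]], ">"),
                                     vapply(out, groundKey, ""))))
      }
      inc <- which(tr$o == b & tr$o_kind == "bnode")
      if (length(inc)) {
        sk <- ifelse(isBlank(tr$s[inc]), paste0("B<", sig[tr$s[inc]], ">"),
                     tr$s[inc])
        toks <- c(toks, paste0("I|", tr$p[inc], "|", sk))
      }
      new[b] <- paste(sort(toks), collapse = ";")
    }
    if (identical(new, sig)) break
    sig <- new
  }
  sig
}

canonicalBnodeLabels <- function(tr) {
  sig <- bnodeSignatures(tr)
  if (!length(sig)) return(character(0))
  ord <- order(sig)
  stats::setNames(paste0("_:b", seq_along(ord)), names(sig)[ord])
}

## ---- serialization ---------------------------------------------------

escapeLiteral <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

validLocal <- function(x) {
  nzchar(x) & grepl("^[A-Za-z0-9_][A-Za-z0-9_.-]*$", x) & !endsWith(x, ".")
}

shortenIri <- function(iri, px) {
  hits <- which(startsWith(iri, px))
  if (length(hits)) {
    ## longest namespace wins
    hits <- hits[order(-nchar(px[hits]))]
    for (h in hits) {
      local <- substring(iri, nchar(px[h]) + 1L)
      if (validLocal(local)) return(paste0(names(px)[h], ":", local))
    }
  }
  paste0("<", iri, ">")
}

renderTerm <- function(term, kind, lang, dt, px) {
  if (kind == "literal") {
    out <- paste0("\"", escapeLiteral(term), "\"")
    if (!is.na(lang)) out <- paste0(out, "@", lang)
    else if (!is.na(dt) && dt != XSD_STRING)
      out <- paste0(out, "^^", shortenIri(dt, px))
    out
  } else if (kind == "bnode") {
    term
  } else {
    shortenIri(term, px)
  }
}

renderTripleLines <- function(tr, px, indent = "") {
  if (!nrow(tr)) return(character(0))
  relab <- canonicalBnodeLabels(tr)
  mp <- function(x, blank) if (length(relab) && blank) unname(relab[x]) else x
  lines <- vapply(seq_len(nrow(tr)), function(i) {
    s <- if (isBlank(tr$s[i])) relab[[tr$s[i]]] else shortenIri(tr$s[i], px)
    p <- if (tr$p[i] == RDF_TYPE) "a" else shortenIri(tr$p[i], px)
    oi <- if (tr$o_kind[i] == "bnode") relab[[tr$o[i]]] else tr$o[i]
    o <- renderTerm(oi, tr$o_kind[i], tr$o_lang[i], tr$o_dt[i], px)
    paste0(indent, s, " ", p, " ", o, " .")
  }, "")
  sort(lines, method = "radix")
}

serializeTrig <- function(ds) {
  px <- prefixes(ds)
  q <- quads(ds)
  out <- sprintf("@prefix %s: <%s> .", names(px), unname(px))
  dft <- q[is.na(q$graph), -1L, drop = FALSE]
  if (nrow(dft)) out <- c(out, "", renderTripleLines(dft, px))
  for (g in namedGraphs(ds)) {
    tr <- q[!is.na(q$graph) & q$graph == g, -1L, drop = FALSE]
    out <- c(out, "", paste0(shortenIri(g, px), " {"),
             renderTripleLines(tr, px, "    "), "}")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

serializeNquads <- function(ds) {
  q <- quads(ds)
  gs <- c(NA_character_, namedGraphs(ds))
  lines <- character(0)
  for (gi in seq_along(gs)) {
    g <- gs[gi]
    tr <- q[if (is.na(g)) is.na(q$graph) else (!is.na(q$graph) & q$graph == g),
            -1L, drop = FALSE]
    if (!nrow(tr)) next
    relab <- canonicalBnodeLabels(tr)
    ## graph-qualified labels keep document-scoped N-Quads labels distinct
    if (length(relab)) relab[] <- sub("^_:b", sprintf("_:g%db", gi - 1L), relab)
    ln <- vapply(seq_len(nrow(tr)), function(i) {
      s <- if (isBlank(tr$s[i])) relab[[tr$s[i]]] else paste0("<", tr$s[i], ">")
      o <- if (tr$o_kind[i] == "bnode") relab[[tr$o[i]]]
           else if (tr$o_kind[i] == "literal") {
             x <- paste0("\"", escapeLiteral(tr$o[i]), "\"")
             if (!is.na(tr$o_lang[i])) paste0(x, "@", tr$o_lang[i])
             else if (!is.na(tr$o_dt[i]) && tr$o_dt[i] != XSD_STRING)
               paste0(x, "^^<", tr$o_dt[i], ">")
             else x
           } else paste0("<", tr$o[i], ">")
      paste0(s, " <", tr$p[i], "> ", o,
             if (is.na(g)) "" else paste0(" <", g, ">"), " .")
    }, "")
    lines <- c(lines, ln)
  }
  paste0(paste(sort(lines, method = "radix"), collapse = "\n"), "\n")
}

#' Serialize an evidence dataset
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param format \code{"trig"} (normative) or \code{"nquads"}.
#' @return a single character scalar holding the document.
#' @seealso \code{\link{parseDataset}}, \code{\link{writeDataset}}
#' @export
serializeDataset <- function(ds, format = c("trig", "nquads")) {
  format <- match.arg(format)
  switch(format, trig = serializeTrig(ds), nquads = serializeNquads(ds))
}

#' @rdname serializeDataset
#' @param path file path to write/read.
#' @export
writeDataset <- function(ds, path, format = c("trig", "nquads")) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(serializeDataset(ds, format)), con, sep = "", useBytes = TRUE)
  invisible(path)
}

#' @rdname serializeDataset
#' @export
readDataset <- function(path, format = c("trig", "nquads")) {
  seeAssert(file.exists(path), "IO_ERROR", sprintf("no such file: %s", path))
  txt <- paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  parseDataset(txt, format)
}

## ---- tokenizer -------------------------------------------------------

## patterns grouped by the first character of the token, so each step
## tries only the few plausible alternatives
tokenDispatch <- local({
  pats <- list(
    at     = list(c("PREFIXD", "^@prefix\\b"), c("BASED", "^@base\\b"),
                  c("LANG", "^@[A-Za-z]+(?:-[A-Za-z0-9]+)*")),
    iri    = list(c("IRI", "^<([^<>\"{}|^`\\\\\\x00-\\x20]*)>")),
    dquote = list(c("STRING", "^(?s)\"\"\"(.*?)\"\"\""),
                  c("STRING", "^\"((?:[^\"\\\\\n]|\\\\.)*)\"")),
    squote = list(c("STRING", "^(?s)'''(.*?)'''"),
                  c("STRING", "^'((?:[^'\\\\\n]|\\\\.)*)'")),
    caret  = list(c("DTMARK", "^\\^\\^")),
    bnode  = list(c("BNODE", "^_:[A-Za-z0-9][A-Za-z0-9_.-]*")),
    number = list(c("NUMBER", "^[+-]?[0-9]+(?:\\.[0-9]+)?"),
                  c("PNAME", "^([A-Za-z][A-Za-z0-9_.-]*)?:((?:[A-Za-z0-9_%]|[._-](?=[A-Za-z0-9_%.-]))(?:[A-Za-z0-9_%.-])*)?")),
    punct  = list(c("PUNCT", "^[{};,.]")),
    word   = list(c("PREFIXD", "^(?i)PREFIX\\b"), c("BASED", "^(?i)BASE\\b"),
                  c("GRAPHKW", "^(?i)GRAPH\\b"), c("BOOL", "^(?:true|false)\\b"),
                  c("PNAME", "^([A-Za-z][A-Za-z0-9_.-]*)?:((?:[A-Za-z0-9_%]|[._-](?=[A-Za-z0-9_%.-]))(?:[A-Za-z0-9_%.-])*)?"),
                  c("A", "^a\\b")),
    colon  = list(c("PNAME", "^:((?:[A-Za-z0-9_%]|[._-](?=[A-Za-z0-9_%.-]))(?:[A-Za-z0-9_%.-])*)?"))
  )
  function(ch) {
    if (ch == "@") pats$at
    else if (ch == "<") pats$iri
    else if (ch == "\"") pats$dquote
    else if (ch == "'") pats$squote
    else if (ch == "^") pats$caret
    else if (ch == "_") pats$bnode
    else if (ch %in% c("{", "}", ";", ",", ".")) pats$punct
    else if (ch == ":") pats$colon
    else if (grepl("^[0-9+-]$", ch)) pats$number
    else pats$word
  }
})

tokenizeRdf <- function(text) {
  ## lines are tokenized independently; only long-quoted strings could
  ## span lines and those are re-joined below when quotes stay open
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  toks <- vector("list", 512L)
  nt <- 0L
  push <- function(type, val, pos) {
    nt <<- nt + 1L
    if (nt > length(toks)) toks <<- c(toks, vector("list", length(toks)))
    toks[[nt]] <<- list(type = type, value = val, pos = pos)
  }
  offset <- 0L
  li <- 1L
  nl <- length(lines)
  while (li <= nl) {
    line <- lines[li]
    lineOffset <- offset
    offset <- offset + nchar(line) + 1L
    li <- li + 1L
    pos <- 1L
    n <- nchar(line)
    while (pos <= n) {
      ch <- substr(line, pos, pos)
      if (ch %in% c(" ", "\t", "\r")) { pos <- pos + 1L; next }
      if (ch == "#") break
      rest <- substr(line, pos, n)
      ## a long-quoted string may continue on following lines
      if ((startsWith(rest, "\"\"\"") && !grepl('^"""(?s).*?"""', rest, perl = TRUE)) ||
          (startsWith(rest, "'''") && !grepl("^'''(?s).*?'''", rest, perl = TRUE))) {
        while (li <= nl) {
          rest <- paste0(rest, "\n", lines[li])
          offset <- offset + nchar(lines[li]) + 1L
          li <- li + 1L
          if (grepl('^(""".*?"""|\'\'\'.*?\'\'\')', rest, perl = TRUE)) break
        }
        line <- rest; pos <- 1L; n <- nchar(line)
        rest <- line
      }
      matched <- FALSE
      for (pat in tokenDispatch(ch)) {
        m <- regexpr(pat[2], rest, perl = TRUE)
        if (m == 1L) {
          len <- attr(m, "match.length")
          val <- substr(rest, 1L, len)
          if (pat[1] %in% c("BNODE", "PNAME")) {
            while (endsWith(val, ".")) {
              val <- substr(val, 1L, nchar(val) - 1L)
              len <- len - 1L
            }
          }
          push(pat[1], val, lineOffset + pos)
          pos <- pos + len
          matched <- TRUE
          break
        }
      }
      if (!matched) {
        lc <- posToLineCol(text, lineOffset + pos)
        seeError("PARSE_ERROR",
                 sprintf("unexpected character '%s' at line %d, column %d",
                         ch, lc[1], lc[2]))
      }
    }
  }
  toks[seq_len(nt)]
}

posToLineCol <- function(text, pos) {
  before <- substr(text, 1L, pos - 1L)
  nl <- gregexpr("\n", before, fixed = TRUE)[[1]]
  if (nl[1] == -1L) c(1L, pos) else c(length(nl) + 1L, pos - nl[length(nl)])
}

unescapeLiteral <- function(x) {
  if (!grepl("\\", x, fixed = TRUE)) return(x)
  out <- character(0)
  i <- 1L; n <- nchar(x)
  while (i <= n) {
    ch <- substr(x, i, i)
    if (ch == "\\" && i < n) {
      nxt <- substr(x, i + 1L, i + 1L)
      rep <- switch(nxt, n = "\n", t = "\t", r = "\r", "\"" = "\"",
                    "'" = "'", "\\" = "\\", b = "\b", f = "\f",
                    u = NA_character_, U = NA_character_, NULL)
      if (is.null(rep)) { out <- c(out, ch); i <- i + 1L; next }
      if (is.na(rep)) {
        w <- if (nxt == "u") 4L else 8L
        code <- strtoi(substr(x, i + 2L, i + 1L + w), 16L)
        out <- c(out, intToUtf8(code))
        i <- i + 2L + w
      } else {
        out <- c(out, rep)
        i <- i + 2L
      }
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

## ---- parser ----------------------------------------------------------

#' Parse a TriG or N-Quads document
#'
#' Parsing then re-serializing yields a dataset isomorphic to the source
#' (blank nodes are bijectively relabelled per graph). Prefixes declared
#' in the document are installed on the resulting dataset on top of the
#' package defaults, so the model vocabulary resolves even for documents
#' that only declare their own namespaces.
#'
#' @param text document text (single string or character vector of lines).
#' @param format \code{"trig"} or \code{"nquads"}.
#' @return an \code{\linkS4class{EvidenceDataset}}.
#' @export
parseDataset <- function(text, format = c("trig", "nquads")) {
  format <- match.arg(format)
  text <- paste(text, collapse = "\n")
  toks <- tokenizeRdf(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$i <- 1L; st$text <- text
  st$prefixes <- character(0)
  st$base <- ""
  rows <- parseDocument(st, nquads = (format == "nquads"))
  px <- defaultPrefixes()
  px[names(st$prefixes)] <- st$prefixes
  ds <- newDataset(px)
  if (nrow(rows)) {
    ## scope blank-node labels per graph
    for (col in c("s", "o")) {
      bl <- if (col == "s") isBlank(rows$s) else rows$o_kind == "bnode"
      gkey <- ifelse(is.na(rows$graph), "", rows$graph)
      rows[[col]][bl] <- paste0("_:", gsub("[^A-Za-z0-9]", "x", gkey[bl]), ".",
                                sub("^_:", "", rows[[col]][bl]))
    }
    rows <- rows[!duplicated(rows), , drop = FALSE]
    row.names(rows) <- NULL
    ds@env$quads <- rows
    ds@env$qkeys <- NULL
  }
  validObject(ds)
  ds
}

peek <- function(st) if (st$i <= length(st$toks)) st$toks[[st$i]] else list(type = "EOF", value = "", pos = nchar(st$text) + 1L)
advance <- function(st) { t <- peek(st); st$i <- st$i + 1L; t }

parseFail <- function(st, tok, what) {
  lc <- posToLineCol(st$text, tok$pos)
  seeError("PARSE_ERROR", sprintf("expected %s but found '%s' at line %d, column %d",
                                  what, tok$value, lc[1], lc[2]))
}

expectPunct <- function(st, ch) {
  t <- advance(st)
  if (t$type != "PUNCT" || t$value != ch) parseFail(st, t, sprintf("'%s'", ch))
  t
}

resolveIriTok <- function(st, tok) {
  v <- sub("^<", "", sub(">$", "", tok$value))
  v <- unescapeLiteral(v)
  if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*:", v)) v <- paste0(st$base, v)
  v
}

resolvePnameTok <- function(st, tok) {
  m <- regmatches(tok$value, regexec("^([^:]*):(.*)$", tok$value))[[1]]
  pfx <- m[2]; local <- m[3]
  ns <- st$prefixes[pfx]
  if (is.na(ns)) {
    lc <- posToLineCol(st$text, tok$pos)
    seeError("PARSE_ERROR", sprintf("undeclared prefix '%s:' at line %d, column %d",
                                    pfx, lc[1], lc[2]))
  }
  paste0(unname(ns), local)
}

## returns list(term, kind, lang, dt)
parseTermObj <- function(st) {
  t <- advance(st)
  switch(t$type,
    IRI   = list(term = resolveIriTok(st, t), kind = "iri", lang = NA, dt = NA),
    PNAME = list(term = resolvePnameTok(st, t), kind = "iri", lang = NA, dt = NA),
    BNODE = list(term = t$value, kind = "bnode", lang = NA, dt = NA),
    NUMBER = list(term = t$value, kind = "literal", lang = NA,
                  dt = paste0(XSD_NS, if (grepl("\\.", t$value)) "decimal" else "integer")),
    BOOL  = list(term = t$value, kind = "literal", lang = NA,
                 dt = paste0(XSD_NS, "boolean")),
    STRING = {
      val <- unescapeLiteral(gsub("^(\"\"\"|'''|\"|')|(\"\"\"|'''|\"|')$", "", t$value))
      nxt <- peek(st)
      if (nxt$type == "LANG") {
        advance(st)
        list(term = val, kind = "literal", lang = sub("^@", "", nxt$value), dt = NA)
      } else if (nxt$type == "DTMARK") {
        advance(st)
        dtok <- advance(st)
        dt <- if (dtok$type == "IRI") resolveIriTok(st, dtok)
              else if (dtok$type == "PNAME") resolvePnameTok(st, dtok)
              else parseFail(st, dtok, "datatype IRI")
        list(term = val, kind = "literal", lang = NA, dt = dt)
      } else {
        list(term = val, kind = "literal", lang = NA, dt = XSD_STRING)
      }
    },
    parseFail(st, t, "RDF term"))
}

parseSubject <- function(st) {
  t <- advance(st)
  switch(t$type,
    IRI   = resolveIriTok(st, t),
    PNAME = resolvePnameTok(st, t),
    BNODE = t$value,
    parseFail(st, t, "subject"))
}

parseVerb <- function(st) {
  t <- advance(st)
  switch(t$type,
    A     = RDF_TYPE,
    IRI   = resolveIriTok(st, t),
    PNAME = resolvePnameTok(st, t),
    parseFail(st, t, "predicate"))
}

## predicate-object list for one subject; returns row list
parsePredicateObjects <- function(st, graph, s, acc) {
  repeat {
    p <- parseVerb(st)
    repeat {
      o <- parseTermObj(st)
      acc[[length(acc) + 1L]] <- list(graph = graph, s = s, p = p, o = o$term,
                                      o_kind = o$kind,
                                      o_lang = if (is.na(o$lang)) NA_character_ else o$lang,
                                      o_dt = if (is.na(o$dt)) NA_character_ else o$dt)
      if (peek(st)$type == "PUNCT" && peek(st)$value == ",") { advance(st); next }
      break
    }
    if (peek(st)$type == "PUNCT" && peek(st)$value == ";") {
      advance(st)
      ## tolerate trailing ';' before '.' or '}'
      if (peek(st)$type == "PUNCT" && peek(st)$value %in% c(".", "}")) break
      next
    }
    break
  }
  acc
}

parseGraphBody <- function(st, graph, acc) {
  repeat {
    t <- peek(st)
    if (t$type == "PUNCT" && t$value == "}") { advance(st); break }
    if (t$type == "EOF") parseFail(st, t, "'}'")
    s <- parseSubject(st)
    acc <- parsePredicateObjects(st, graph, s, acc)
    nxt <- peek(st)
    if (nxt$type == "PUNCT" && nxt$value == ".") advance(st)
    else if (!(nxt$type == "PUNCT" && nxt$value == "}")) parseFail(st, nxt, "'.' or '}'")
  }
  acc
}

parseDocument <- function(st, nquads = FALSE) {
  acc <- list()
  repeat {
    t <- peek(st)
    if (t$type == "EOF") break
    if (t$type == "PREFIXD") {
      sparqlStyle <- !startsWith(t$value, "@")
      advance(st)
      ptok <- advance(st)
      if (ptok$type != "PNAME") parseFail(st, ptok, "prefix declaration")
      pfx <- sub(":.*$", "", ptok$value)
      itok <- advance(st)
      if (itok$type != "IRI") parseFail(st, itok, "namespace IRI")
      st$prefixes[pfx] <- resolveIriTok(st, itok)
      if (!sparqlStyle) expectPunct(st, ".")
      else if (peek(st)$type == "PUNCT" && peek(st)$value == ".") advance(st)
      next
    }
    if (t$type == "BASED") {
      advance(st)
      itok <- advance(st)
      if (itok$type != "IRI") parseFail(st, itok, "base IRI")
      st$base <- resolveIriTok(st, itok)
      if (peek(st)$type == "PUNCT" && peek(st)$value == ".") advance(st)
      next
    }
    if (!nquads && t$type == "GRAPHKW") { advance(st); t <- peek(st) }
    ## graph block?  <iri> { ... }   (only in TriG)
    if (!nquads && t$type %in% c("IRI", "PNAME")) {
      save <- st$i
      g <- parseSubject(st)
      if (peek(st)$type == "PUNCT" && peek(st)$value == "{") {
        advance(st)
        acc <- parseGraphBody(st, g, acc)
        if (peek(st)$type == "PUNCT" && peek(st)$value == ".") advance(st)
        next
      }
      st$i <- save
    }
    ## default-graph statement (TriG) or quad line (N-Quads)
    s <- parseSubject(st)
    if (nquads) {
      p <- parseVerb(st)
      o <- parseTermObj(st)
      g <- NA_character_
      nxt <- peek(st)
      if (nxt$type %in% c("IRI", "PNAME")) g <- parseSubject(st)
      expectPunct(st, ".")
      acc[[length(acc) + 1L]] <- list(graph = g, s = s, p = p, o = o$term,
                                      o_kind = o$kind,
                                      o_lang = if (is.na(o$lang)) NA_character_ else o$lang,
                                      o_dt = if (is.na(o$dt)) NA_character_ else o$dt)
    } else {
      acc <- parsePredicateObjects(st, NA_character_, s, acc)
      expectPunct(st, ".")
    }
  }
  if (!length(acc)) return(emptyQuads())
  col <- function(f) vapply(acc, function(r) r[[f]], NA_character_)
  fastDF(list(graph = col("graph"), s = col("s"), p = col("p"), o = col("o"),
              o_kind = col("o_kind"), o_lang = col("o_lang"),
              o_dt = col("o_dt")))
}

## ---- isomorphism -----------------------------------------------------

groundKeyRows <- function(tr, map = NULL) {
  s <- tr$s; o <- tr$o
  if (!is.null(map)) {
    bs <- isBlank(s); s[bs] <- unname(map[s[bs]])
    bo <- tr$o_kind == "bnode"; o[bo] <- unname(map[o[bo]])
  }
  paste(s, tr$p, o, tr$o_kind, tr$o_lang, tr$o_dt, sep = "\r")
}

graphsIsomorphic <- function(t1, t2) {
  if (nrow(t1) != nrow(t2)) return(FALSE)
  b1 <- unique(c(t1$s[isBlank(t1$s)], t1$o[t1$o_kind == "bnode"]))
  b2 <- unique(c(t2$s[isBlank(t2$s)], t2$o[t2$o_kind == "bnode"]))
  if (length(b1) != length(b2)) return(FALSE)
  if (!length(b1))
    return(identical(sort(groundKeyRows(t1)), sort(groundKeyRows(t2))))
  s1 <- bnodeSignatures(t1)
  s2 <- bnodeSignatures(t2)
  if (!identical(sort(unname(s1)), sort(unname(s2)))) return(FALSE)
  key2 <- sort(groundKeyRows(t2))
  order1 <- names(sort(s1))
  search <- function(idx, map, used) {
    if (idx > length(order1)) {
      return(identical(sort(groundKeyRows(t1, map)), key2))
    }
    b <- order1[idx]
    cand <- setdiff(names(s2)[s2 == s1[[b]]], used)
    for (cb in cand) {
      map[b] <- cb
      if (search(idx + 1L, map, c(used, cb))) return(TRUE)
    }
    FALSE
  }
  search(1L, stats::setNames(character(0), character(0)), character(0))
}

#' Test dataset isomorphism
#'
#' Two datasets are isomorphic when they have the same graph names and,
#' per graph (including the default graph), a bijection of blank nodes
#' maps one triple set exactly onto the other. Graph names are compared
#' literally; prefix maps are presentation and are ignored.
#'
#' @param ds1,ds2 \code{\linkS4class{EvidenceDataset}} objects.
#' @return logical scalar.
#' @export
isomorphicDatasets <- function(ds1, ds2) {
  q1 <- quads(ds1); q2 <- quads(ds2)
  gkey <- function(q) ifelse(is.na(q$graph), "\rdefault\r", q$graph)
  sp1 <- split(seq_len(nrow(q1)), gkey(q1))
  sp2 <- split(seq_len(nrow(q2)), gkey(q2))
  gs <- union(names(sp1), names(sp2))
  for (g in gs) {
    i1 <- sp1[[g]]; i2 <- sp2[[g]]
    if (is.null(i1) || is.null(i2)) return(FALSE)
    if (!graphsIsomorphic(q1[i1, -1L, drop = FALSE], q2[i2, -1L, drop = FALSE]))
      return(FALSE)
  }
  TRUE
}
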