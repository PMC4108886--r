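## Shared test helpers: memoized fixtures, an independent reachability
## oracle (igraph), and a SPARQL runner (python + rdflib) used to
## cross-check the emitted queries against the programmatic answers.

.fixtureCache <- new.env(parent = emptyenv())

gsFx <- function(variant = "full") {
  if (is.null(.fixtureCache[[variant]]))
    .fixtureCache[[variant]] <- buildGsCaseStudy(variant)
  .fixtureCache[[variant]]
}

## Independent closure oracle: rebuild the expanded premise relation
## E = idf  union  (idf o has_conjunctive_part) straight from the quad
## table and take igraph reachability.
oracleClosure <- function(ds, a) {
  q <- quads(ds)
  voc <- vocabulary(ds)
  dft <- is.na(q$graph)
  idf <- q[dft & q$p == voc[["is_directly_inferred_from"]], c("s", "o")]
  prt <- q[dft & q$p == voc[["has_conjunctive_part"]], c("s", "o")]
  edges <- idf
  for (i in seq_len(nrow(idf))) {
    parts <- prt$o[prt$s == idf$o[i]]
    if (length(parts))
      edges <- rbind(edges, data.frame(s = idf$s[i], o = parts,
                                       stringsAsFactors = FALSE))
  }
  nodes <- unique(c(edges$s, edges$o, a))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  out <- names(igraph::subcomponent(g, a, mode = "out"))
  sort(setdiff(out, a))
}

## exhaustive bnode-bijection search (small graphs), independent of the
## package's signature-pruned implementation
bruteGraphIso <- function(t1, t2) {
  key <- function(tr, map) {
    s <- tr$s; o <- tr$o
    bs <- startsWith(s, "_:"); s[bs] <- map[s[bs]]
    bo <- tr$o_kind == "bnode"; o[bo] <- map[o[bo]]
    sort(paste(s, tr$p, o, tr$o_kind, tr$o_lang, tr$o_dt, sep = "\r"))
  }
  b1 <- unique(c(t1$s[startsWith(t1$s, "_:")], t1$o[t1$o_kind == "bnode"]))
  b2 <- unique(c(t2$s[startsWith(t2$s, "_:")], t2$o[t2$o_kind == "bnode"]))
  if (length(b1) != length(b2) || nrow(t1) != nrow(t2)) return(FALSE)
  if (!length(b1)) return(identical(key(t1, character(0)), key(t2, character(0))))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (p in perms(b2)) {
    map <- stats::setNames(p, b1)
    if (identical(key(t1, map), key(t2, stats::setNames(b2, b2)))) return(TRUE)
  }
  FALSE
}

sparqlScriptPath <- local({
  path <- NULL
  function() {
    if (is.null(path)) {
      path <<- tempfile(fileext = ".py")
      writeLines(c(
        "import sys",
        "from rdflib import Dataset",
        "ds = Dataset()",
        "ds.parse(sys.argv[1], format='trig')",
        "for row in ds.query(open(sys.argv[2]).read()):",
        "    print('\\t'.join('' if v is None else str(v) for v in row))"),
        path)
    }
    path
  }
})

## run a SPARQL SELECT over the TriG serialization; returns a character
## matrix (one row per solution)
runSparql <- function(ds, query) {
  trig <- tempfile(fileext = ".trig")
  rq <- tempfile(fileext = ".rq")
  on.exit(unlink(c(trig, rq)))
  writeDataset(ds, trig, "trig")
  writeLines(query, rq)
  out <- suppressWarnings(
    system2("python", c(sparqlScriptPath(), trig, rq), stdout = TRUE,
            stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("SPARQL engine failed: ", paste(out, collapse = "\n"))
  if (!length(out)) return(matrix(character(0), ncol = 1))
  do.call(rbind, strsplit(out, "\t", fixed = TRUE))
}

sparqlCol <- function(m, i = 1L) if (!nrow(m)) character(0) else sort(unique(m[, i]))
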