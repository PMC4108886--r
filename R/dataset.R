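#' Default prefix map
#'
#' The namespaces installed by \code{\link{newDataset}} when no prefixes
#' are supplied: the RDF/RDFS/OWL/XSD standard namespaces, \code{rdo:} for
#' the reasoning-and-discourse vocabulary (the claim/provenance model),
#' \code{ann:} for dataset-local annotation properties (assertion roles)
#' and \code{ex:} for case-study resources. The \code{rdo:} and \code{ex:}
#' bases are conventions of this package, not resolvable IRIs; supplying a
#' different \code{rdo} namespace rebases the whole vocabulary.
#'
#' @return named character vector mapping prefix to namespace IRI.
#' @export
defaultPrefixes <- function() {
  c(rdf  = RDF_NS,
    rdfs = RDFS_NS,
    owl  = OWL_NS,
    xsd  = XSD_NS,
    rdo  = "http://example.org/rdo#",
    ann  = "http://example.org/see-annotation#",
    ex   = "http://example.org/gsexample#")
}

## Vocabulary of the claim/provenance model, resolved against a base.
## is_inferred_from is the transitive super-relation of
## is_directly_inferred_from; is_based_on_report / is_based_on_text are the
## derived provenance relations materialized by the inference functions.
rdoTerms <- function(rdoBase, annBase) {
  core <- c(
    assertion   = "assertion",
    proposition = "proposition",
    text        = "text",
    report      = "report",
    report_part = "report_part",
    agent       = "agent",
    asserts                  = "asserts",
    is_assertion_made_by     = "is_assertion_made_by",
    is_assertion_made_in     = "is_assertion_made_in",
    is_directly_inferred_from = "is_directly_inferred_from",
    is_inferred_from         = "is_inferred_from",
    has_conjunctive_part     = "has_conjunctive_part",
    has_lexical_structure    = "has_lexical_structure",
    is_expressed_as          = "is_expressed_as",
    is_part_of               = "is_part_of",
    has_initials             = "has_initials",
    has_url                  = "has_url",
    is_based_on_report       = "is_based_on_report",
    is_based_on_text         = "is_based_on_text")
  out <- stats::setNames(paste0(rdoBase, core), names(core))
  c(out, has_role = paste0(annBase, "has_role"))
}

#' Create an empty evidence dataset
#'
#' @param prefixes named character vector of prefix/namespace pairs;
#'   entries override \code{\link{defaultPrefixes}}. The \code{rdo} and
#'   \code{ann} namespaces determine where the model vocabulary lives.
#' @return an empty \code{\linkS4class{EvidenceDataset}}.
#' @examples
#' ds <- newDataset()
#' ds
#' @export
newDataset <- function(prefixes = defaultPrefixes()) {
  if (length(prefixes)) {
    seeAssert(is.character(prefixes) && !is.null(names(prefixes)) &&
                all(nzchar(names(prefixes))),
              "BAD_PREFIX", "prefixes must be a named character vector")
    if (!all(isAbsoluteIri(prefixes)))
      seeError("BAD_PREFIX",
               paste("invalid namespace IRI:",
                     paste(prefixes[!isAbsoluteIri(prefixes)], collapse = ", ")))
  }
  px <- defaultPrefixes()
  px[names(prefixes)] <- prefixes
  e <- new.env(parent = emptyenv())
  e$quads <- emptyQuads()
  e$prefixes <- px[order(names(px))]
  e$vocab <- rdoTerms(px[["rdo"]], px[["ann"]])
  e$counters <- new.env(parent = emptyenv())
  e$bnode <- 0L
  new("EvidenceDataset", env = e)
}

#' Access dataset contents
#'
#' \code{quads} returns the full quad table (default graph rows have
#' \code{NA} in the \code{graph} column), \code{defaultGraph} the
#' default-graph triples, \code{namedGraphs} the named-graph IRIs,
#' \code{namedGraph} one graph's triples, \code{prefixes} the prefix map
#' and \code{vocabulary} the resolved model vocabulary.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @return data frames of triples/quads, or character vectors.
#' @export
quads <- function(ds) ds@env$quads

#' @rdname quads
#' @export
defaultGraph <- function(ds) {
  q <- ds@env$quads
  q[is.na(q$graph), -1L, drop = FALSE]
}

#' @rdname quads
#' @export
namedGraphs <- function(ds) {
  g <- unique(ds@env$quads$graph)
  sort(g[!is.na(g)])
}

#' @rdname quads
#' @param graphIri IRI naming a graph in the dataset.
#' @export
namedGraph <- function(ds, graphIri) {
  q <- ds@env$quads
  hit <- !is.na(q$graph) & q$graph == graphIri
  seeAssert(any(hit), "UNKNOWN_GRAPH",
            sprintf("no named graph <%s> in dataset", graphIri))
  q[hit, -1L, drop = FALSE]
}

#' @rdname quads
#' @export
prefixes <- function(ds) ds@env$prefixes

#' @rdname quads
#' @export
vocabulary <- function(ds) ds@env$vocab

#' Build a triple table row
#'
#' Convenience constructor for the triple data frames consumed by
#' \code{\link{addNamedGraph}} and \code{\link{addTriples}}. Subjects may
#' be IRIs or blank nodes (\code{"_:" } prefix); objects may additionally
#' be \code{\link{rdfLiteral}} values.
#'
#' @param s,p,o subject, predicate, object.
#' @return one-row data frame in the package's triple layout.
#' @examples
#' triple("http://ex.org/assay-1",
#'        "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
#'        "http://ex.org/gamma_ghs_assay")
#' @export
triple <- function(s, p, o) {
  seeAssert(is.character(s) && length(s) == 1L && nzchar(s),
            "BAD_TERM", "subject must be an IRI or blank node")
  seeAssert(is.character(p) && length(p) == 1L && isAbsoluteIri(p),
            "BAD_TERM", "predicate must be an absolute IRI")
  if (isLiteral(o)) {
    ## RDF 1.1: a simple literal is an xsd:string
    fastDF(list(s = s, p = p, o = o$value, o_kind = "literal",
                o_lang = if (is.null(o$lang)) NA_character_ else o$lang,
                o_dt = if (!is.null(o$lang)) NA_character_
                       else if (is.null(o$datatype)) XSD_STRING else o$datatype))
  } else {
    seeAssert(is.character(o) && length(o) == 1L && nzchar(o),
              "BAD_TERM", "object must be an IRI, blank node or rdfLiteral")
    fastDF(list(s = s, p = p, o = o,
                o_kind = if (isBlank(o)) "bnode" else "iri",
                o_lang = NA_character_, o_dt = NA_character_))
  }
}

## cheap data.frame constructor (columns already validated)
fastDF <- function(cols) {
  structure(cols, class = "data.frame",
            row.names = .set_row_names(length(cols[[1]])))
}

quadKeys <- function(graph, tr) {
  paste(graph, tr$s, tr$p, tr$o, tr$o_kind, tr$o_lang, tr$o_dt, sep = "\r")
}

## Internal: append triple rows to a graph (NA = default), set semantics.
appendQuads <- function(ds, triples, graph = NA_character_) {
  n <- nrow(triples)
  if (!n) return(invisible(ds))
  e <- ds@env
  if (is.null(e$qkeys)) e$qkeys <- quadKeys(e$quads$graph, e$quads)
  graph <- rep_len(graph, n)
  keys <- quadKeys(graph, triples)
  new <- !(keys %in% e$qkeys) & !duplicated(keys)
  if (!any(new)) return(invisible(ds))
  q <- e$quads
  e$quads <- fastDF(list(graph = c(q$graph, graph[new]),
                         s = c(q$s, triples$s[new]),
                         p = c(q$p, triples$p[new]),
                         o = c(q$o, triples$o[new]),
                         o_kind = c(q$o_kind, triples$o_kind[new]),
                         o_lang = c(q$o_lang, triples$o_lang[new]),
                         o_dt = c(q$o_dt, triples$o_dt[new])))
  names(e$quads) <- quadColumns
  e$qkeys <- c(e$qkeys, keys[new])
  invisible(ds)
}

#' Add triples to the default graph
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param triples data frame built from \code{\link{triple}} rows.
#' @return the dataset, invisibly (modified in place).
#' @export
addTriples <- function(ds, triples) {
  appendQuads(ds, triples, NA_character_)
}

addTriple <- function(ds, s, p, o, graph = NA_character_) {
  appendQuads(ds, triple(s, p, o), graph)
}

#' Add a named graph (a proposition subject graph)
#'
#' Installs \code{triples} as the named graph \code{graphIri}. Proposition
#' subjects are stored this way: the proposition's IRI names the graph
#' that represents \emph{what} is claimed.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param graphIri IRI of the new graph; must not already exist.
#' @param triples non-empty triple data frame (see \code{\link{triple}}).
#' @return \code{graphIri}, invisibly.
#' @export
addNamedGraph <- function(ds, graphIri, triples) {
  seeAssert(isAbsoluteIri(graphIri), "BAD_TERM",
            "graph IRI must be an absolute IRI")
  if (graphIri %in% namedGraphs(ds))
    seeError("DUPLICATE_GRAPH", sprintf("named graph <%s> already exists", graphIri))
  if (is.null(triples) || !nrow(triples))
    seeError("EMPTY_SUBJECT", "a proposition graph needs at least one triple")
  appendQuads(ds, triples, graphIri)
  invisible(graphIri)
}

## ---- IRI minting -----------------------------------------------------

exNamespace <- function(ds) ds@env$prefixes[["ex"]]

iriKnown <- function(ds, iri) {
  q <- ds@env$quads
  iri %in% q$s || iri %in% q$o[q$o_kind != "literal"] ||
    iri %in% q$graph[!is.na(q$graph)]
}

#' Mint a fresh IRI in the example namespace
#'
#' Fresh IRIs use a monotone per-kind counter with human-readable slugs
#' (\code{assertion-1}, \code{proposition-1}, ...). An explicit
#' \code{slug} overrides the counter; reusing an existing IRI is an error,
#' so every builder mints IRIs not previously present.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param kind slug stem, e.g. \code{"proposition"}.
#' @param slug optional explicit local name.
#' @return the new IRI (not yet used in any triple).
#' @export
mintIri <- function(ds, kind, slug = NULL) {
  ns <- exNamespace(ds)
  if (!is.null(slug)) {
    iri <- paste0(ns, slug)
    if (iriKnown(ds, iri))
      seeError("IRI_EXISTS", sprintf("IRI <%s> is already in use", iri))
    return(iri)
  }
  cnt <- ds@env$counters
  repeat {
    n <- (if (is.null(cnt[[kind]])) 0L else cnt[[kind]]) + 1L
    cnt[[kind]] <- n
    iri <- paste0(ns, kind, "-", n)
    if (!iriKnown(ds, iri)) return(iri)
  }
}

mintBnode <- function(ds) {
  ds@env$bnode <- ds@env$bnode + 1L
  paste0("_:n", ds@env$bnode)
}
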