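## Inference closure and derived provenance relations.
##
## The closure is computed by graph traversal over the premise relation
## E = is_directly_inferred_from, expanded through composites: when a
## conclusion is directly inferred from a composite assertion, the
## composite's conjunctive parts count as premises too (both the
## composite and its parts are reported). This materializes, as explicit
## closure rules, the entailments a DL reasoner would derive from the
## transitive super-relation and the conjunction axioms.

## edge tables of the default graph
inferenceEdges <- function(ds) {
  q <- quads(ds)
  voc <- vocabulary(ds)
  dft <- is.na(q$graph)
  list(idf  = q[dft & q$p == voc[["is_directly_inferred_from"]], c("s", "o")],
       part = q[dft & q$p == voc[["has_conjunctive_part"]], c("s", "o")])
}

## successors of x under E: idf targets plus parts of composite idf targets
eSuccessors <- function(edges, x) {
  direct <- edges$idf$o[edges$idf$s == x]
  parts <- edges$part$o[edges$part$s %in% direct]
  unique(c(direct, parts))
}

ePredecessors <- function(edges, x) {
  direct <- edges$idf$s[edges$idf$o == x]
  comps <- edges$part$s[edges$part$o == x]
  viaComp <- edges$idf$s[edges$idf$o %in% comps]
  unique(c(direct, viaComp))
}

bfs <- function(start, step) {
  seen <- character(0)
  frontier <- step(start)
  while (length(frontier)) {
    frontier <- setdiff(frontier, c(seen, start))
    seen <- c(seen, frontier)
    frontier <- unique(unlist(lapply(frontier, step), use.names = FALSE))
  }
  sort(seen)
}

#' Premise relations of an assertion
#'
#' \code{directPremises} returns exactly the targets of the assertion's
#' \code{is_directly_inferred_from} links. \code{premisesClosure} returns
#' every assertion the given one is directly or indirectly inferred from:
#' the reachability set over direct-inference links expanded through
#' composite assertions (composites encountered are expanded into their
#' conjunctive parts, and both are reported); the assertion itself is
#' excluded. \code{conclusionsClosure} is the inverse traversal. Closure
#' is plain reachability, so it is well defined even on cyclic inference
#' structures.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param assertion assertion IRI.
#' @return character vector of assertion IRIs (sorted).
#' @export
directPremises <- function(ds, assertion) {
  requireAssertion(ds, assertion)
  edges <- inferenceEdges(ds)
  sort(unique(edges$idf$o[edges$idf$s == assertion]))
}

#' @rdname directPremises
#' @export
premisesClosure <- function(ds, assertion) {
  requireAssertion(ds, assertion)
  edges <- inferenceEdges(ds)
  bfs(assertion, function(x) eSuccessors(edges, x))
}

#' @rdname directPremises
#' @export
conclusionsClosure <- function(ds, assertion) {
  requireAssertion(ds, assertion)
  edges <- inferenceEdges(ds)
  bfs(assertion, function(x) ePredecessors(edges, x))
}

## reports/parts reachable from a made_in target (which may be a part or
## directly a report)
resolveProvenance <- function(ds, madeIn) {
  q <- quads(ds)
  voc <- vocabulary(ds)
  dft <- is.na(q$graph)
  isReport <- any(dft & q$s == madeIn & q$p == RDF_TYPE & q$o == voc[["report"]])
  if (isReport) return(list(report = madeIn, part = character(0), text = character(0)))
  parents <- q$o[dft & q$s == madeIn & q$p == voc[["is_part_of"]]]
  texts <- q$o[dft & q$s == madeIn & q$p == voc[["is_expressed_as"]]]
  list(report = parents, part = madeIn, text = texts)
}

#' Reports and texts an assertion is based on
#'
#' Collects, over the assertion's premises closure (and, by default, the
#' assertion itself), every report part the member assertions were made
#' in, the parent reports of those parts (or directly linked reports),
#' and the texts expressing the parts. These are the derived
#' is-based-on-report / is-based-on-text relations.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param assertion assertion IRI.
#' @param includeSelf include the assertion's own provenance (default
#'   TRUE).
#' @return list with sorted character vectors \code{reports},
#'   \code{texts}, \code{report_parts}.
#' @export
basedOn <- function(ds, assertion, includeSelf = TRUE) {
  requireAssertion(ds, assertion)
  nodes <- premisesClosure(ds, assertion)
  if (includeSelf) nodes <- c(assertion, nodes)
  q <- quads(ds)
  voc <- vocabulary(ds)
  dft <- is.na(q$graph)
  made <- q$o[dft & q$s %in% nodes & q$p == voc[["is_assertion_made_in"]]]
  out <- list(reports = character(0), texts = character(0),
              report_parts = character(0))
  for (m in unique(made)) {
    pv <- resolveProvenance(ds, m)
    out$reports <- c(out$reports, pv$report)
    out$texts <- c(out$texts, pv$text)
    out$report_parts <- c(out$report_parts, pv$part)
  }
  lapply(out, function(x) sort(unique(x)))
}

requireKnownIri <- function(ds, iri) {
  seeAssert(iriKnown(ds, iri), "UNKNOWN_RESOURCE",
            sprintf("IRI <%s> does not occur in the dataset", iri))
}

#' Index lookups over the assertion/provenance structure
#'
#' \code{assertionsInReport} finds assertions made in a report (directly
#' or via one of its parts); \code{assertionsByAgent} those made by an
#' agent; \code{assertionsOnSubject} all assertions sharing a subject
#' proposition; \code{agentsAsserting} the agents making assertions on a
#' subject. Unknown target IRIs are an error.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param report,agent,proposition target IRIs.
#' @return sorted character vector of IRIs.
#' @export
assertionsInReport <- function(ds, report) {
  requireKnownIri(ds, report)
  q <- quads(ds)
  voc <- vocabulary(ds)
  dft <- is.na(q$graph)
  parts <- q$s[dft & q$p == voc[["is_part_of"]] & q$o == report]
  hit <- dft & q$p == voc[["is_assertion_made_in"]] & q$o %in% c(report, parts)
  sort(unique(q$s[hit]))
}

#' @rdname assertionsInReport
#' @export
assertionsByAgent <- function(ds, agent) {
  requireKnownIri(ds, agent)
  q <- quads(ds)
  voc <- vocabulary(ds)
  sort(unique(q$s[is.na(q$graph) & q$p == voc[["is_assertion_made_by"]] &
                    q$o == agent]))
}

#' @rdname assertionsInReport
#' @export
assertionsOnSubject <- function(ds, proposition) {
  requireKnownIri(ds, proposition)
  q <- quads(ds)
  voc <- vocabulary(ds)
  sort(unique(q$s[is.na(q$graph) & q$p == voc[["asserts"]] & q$o == proposition]))
}

#' @rdname assertionsInReport
#' @export
agentsAsserting <- function(ds, proposition) {
  as <- assertionsOnSubject(ds, proposition)
  sort(unique(unlist(lapply(as, assertingAgents, ds = ds), use.names = FALSE)))
}

#' Detect inference cycles
#'
#' Enumerates simple cycles of the expanded premise relation (bounded).
#' Open-world evidence records are not required to be acyclic, so cycles
#' are reported rather than rejected; closure functions remain well
#' defined on them.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param maxCycles stop after this many cycles.
#' @return list of cycles, each a character vector of assertion IRIs
#'   (cycle start repeated at the end is omitted).
#' @export
detectCycles <- function(ds, maxCycles = 100L) {
  edges <- inferenceEdges(ds)
  nodes <- sort(unique(c(edges$idf$s, edges$idf$o, edges$part$o)))
  cycles <- list()
  for (v in nodes) {
    if (length(cycles) >= maxCycles) break
    ## simple cycles whose lexicographically smallest node is v
    dfs <- function(node, path) {
      if (length(cycles) >= maxCycles) return(invisible())
      for (nx in eSuccessors(edges, node)) {
        if (nx == v) {
          cycles[[length(cycles) + 1L]] <<- c(path, node)
        } else if (nx > v && !(nx %in% path) && nx != node) {
          dfs(nx, c(path, node))
        }
      }
    }
    dfs(v, character(0))
  }
  cycles
}

#' Materialize inferred relations into a dedicated named graph
#'
#' Writes the transitive \code{is_inferred_from} closure and the derived
#' \code{is_based_on_report} / \code{is_based_on_text} relations of every
#' assertion into the named graph \code{urn:see:inferred}, so exported
#' TriG carries the entailments explicitly.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param graphIri name of the materialization graph.
#' @return the dataset, invisibly.
#' @export
materializeInferred <- function(ds, graphIri = "urn:see:inferred") {
  q <- quads(ds)
  voc <- vocabulary(ds)
  as <- sort(unique(q$s[is.na(q$graph) & q$p == RDF_TYPE & q$o == voc[["assertion"]]]))
  rows <- list()
  for (a in as) {
    for (p in premisesClosure(ds, a))
      rows[[length(rows) + 1L]] <- triple(a, voc[["is_inferred_from"]], p)
    bo <- basedOn(ds, a)
    for (r in bo$reports)
      rows[[length(rows) + 1L]] <- triple(a, voc[["is_based_on_report"]], r)
    for (tx in bo$texts)
      rows[[length(rows) + 1L]] <- triple(a, voc[["is_based_on_text"]], tx)
  }
  if (length(rows)) addNamedGraph(ds, graphIri, do.call(rbind, rows))
  invisible(ds)
}
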