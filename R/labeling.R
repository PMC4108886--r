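## Label nomenclature.
##
## Proposition labels are derived from the resources of the subject graph
## using Manchester-syntax keywords ("some", "and", "Type"); assertion
## labels are "! P ! A" where P joins the proposition labels with " AND "
## and A joins the asserting agents' initials with single spaces. A
## leading exclamation mark singles out assertions at a glance.

## rdfs:label of a resource in the default graph, else local-name fallback
## with underscores replaced by spaces.
resourceLabel <- function(ds, iri) {
  q <- quads(ds)
  hit <- is.na(q$graph) & q$s == iri & q$p == RDFS_LABEL & q$o_kind == "literal"
  if (any(hit)) {
    lab <- q$o[hit][1]
    if (nzchar(lab)) return(lab)
  }
  gsub("_", " ", localName(iri))
}

## Property labels drop a leading "is_"/"has_" when no rdfs:label exists:
## "is_isolated_from" prints as "isolated from".
propertyLabel <- function(ds, iri) {
  q <- quads(ds)
  hit <- is.na(q$graph) & q$s == iri & q$p == RDFS_LABEL & q$o_kind == "literal"
  if (any(hit) && nzchar(q$o[hit][1])) return(q$o[hit][1])
  local <- localName(iri)
  local <- sub("^(is|has)_", "", local)
  gsub("_", " ", local)
}

#' Render a class expression as a Manchester-syntax-flavoured label
#'
#' Named classes render as their label, existential restrictions as
#' \code{"<property> some <filler>"} and intersections join their
#' operands with \code{" and "}; nested non-named operands are
#' parenthesized.
#'
#' @param expr a \code{\linkS4class{ClassExpression}}.
#' @param ds optional \code{\linkS4class{EvidenceDataset}} supplying
#'   \code{rdfs:label}s; without it, IRI local names are used.
#' @return character scalar.
#' @examples
#' renderExpression(ceSome("http://ex.org/is_isolated_from",
#'                         "http://ex.org/rat_liver"))
#' @export
renderExpression <- function(expr, ds = NULL) {
  lab <- function(iri) if (is.null(ds)) gsub("_", " ", localName(iri)) else resourceLabel(ds, iri)
  plab <- function(iri) {
    if (is.null(ds)) gsub("_", " ", sub("^(is|has)_", "", localName(iri)))
    else propertyLabel(ds, iri)
  }
  wrap <- function(op) {
    r <- renderExpression(op, ds)
    if (op@variant == "named") r else paste0("(", r, ")")
  }
  switch(expr@variant,
    named = lab(expr@iri),
    some = paste(plab(expr@property), "some", wrap(expr@filler)),
    intersection = paste(vapply(expr@operands, wrap, ""), collapse = " and "))
}

## Match the OWL 2 RDF mapping of "(A and related_to some B)" in a
## proposition graph. Returns a list(classA, property, classB) or NULL.
matchSomeSome <- function(tr) {
  ix <- which(tr$p == OWL_INTERSECTION)
  for (i in ix) {
    cnode <- tr$s[i]; l1 <- tr$o[i]
    firstA <- tr$o[tr$s == l1 & tr$p == RDF_FIRST & tr$o_kind == "iri"]
    l2 <- tr$o[tr$s == l1 & tr$p == RDF_REST & tr$o_kind == "bnode"]
    if (length(firstA) != 1L || length(l2) != 1L) next
    rnode <- tr$o[tr$s == l2 & tr$p == RDF_FIRST & tr$o_kind == "bnode"]
    nilEnd <- any(tr$s == l2 & tr$p == RDF_REST & tr$o == RDF_NIL)
    if (length(rnode) != 1L || !nilEnd) next
    prop <- tr$o[tr$s == rnode & tr$p == OWL_ON_PROPERTY]
    fill <- tr$o[tr$s == rnode & tr$p == OWL_SOME_VALUES & tr$o_kind == "iri"]
    inst <- tr$s[tr$p == RDF_TYPE & tr$o == cnode]
    if (length(prop) != 1L || length(fill) != 1L || !length(inst)) next
    return(list(classA = firstA, property = prop, classB = fill))
  }
  NULL
}

#' Label of a proposition derived from its subject graph
#'
#' Supported graph shapes: the existential pattern "(A and related_to
#' some B)" renders as \code{"some <A> <related to> some <B>"}; a single
#' type triple as \code{"<individual> Type: <class>"}; a single property
#' triple as \code{"<subject> <property> <object>"}. Any other shape
#' falls back to the label \code{"(complex subject)"} with a warning.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param proposition proposition IRI (must name a graph in \code{ds}).
#' @return character scalar.
#' @export
propositionLabel <- function(ds, proposition) {
  tr <- namedGraph(ds, proposition)
  ss <- matchSomeSome(tr)
  if (!is.null(ss))
    return(paste("some", resourceLabel(ds, ss$classA),
                 propertyLabel(ds, ss$property),
                 "some", resourceLabel(ds, ss$classB)))
  if (nrow(tr) == 1L) {
    if (tr$p == RDF_TYPE && tr$o_kind == "iri")
      return(paste(resourceLabel(ds, tr$s), "Type:", resourceLabel(ds, tr$o)))
    obj <- if (tr$o_kind == "literal") tr$o else resourceLabel(ds, tr$o)
    return(paste(resourceLabel(ds, tr$s), propertyLabel(ds, tr$p), obj))
  }
  warning(sprintf("proposition <%s> has an unsupported graph shape; using fallback label",
                  proposition), call. = FALSE)
  "(complex subject)"
}

## asserts targets of an assertion, in insertion order.
assertedPropositions <- function(ds, assertion) {
  q <- quads(ds)
  voc <- vocabulary(ds)
  q$o[is.na(q$graph) & q$s == assertion & q$p == voc[["asserts"]]]
}

assertingAgents <- function(ds, assertion) {
  q <- quads(ds)
  voc <- vocabulary(ds)
  q$o[is.na(q$graph) & q$s == assertion & q$p == voc[["is_assertion_made_by"]]]
}

agentInitials <- function(ds, agent) {
  q <- quads(ds)
  voc <- vocabulary(ds)
  hit <- is.na(q$graph) & q$s == agent & q$p == voc[["has_initials"]]
  if (any(hit)) q$o[hit][1] else gsub("_", " ", localName(agent))
}

#' Label of an assertion: "! P ! A"
#'
#' Recomputes the label from the dataset: \code{P} is the concatenation
#' of the asserted propositions' labels joined by \code{" AND "}, and
#' \code{A} the asserting agents' initials separated by spaces. A pure
#' function of the dataset.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param assertion assertion IRI.
#' @return character scalar, e.g.
#'   \code{"! some GS-enzyme isolated from some rat liver ! AM"}.
#' @export
assertionLabel <- function(ds, assertion) {
  props <- assertedPropositions(ds, assertion)
  seeAssert(length(props) > 0L, "NO_SUBJECT",
            sprintf("assertion <%s> asserts nothing", assertion))
  plabs <- vapply(props, function(p) {
    if (p %in% namedGraphs(ds)) propositionLabel(ds, p) else resourceLabel(ds, p)
  }, "")
  agents <- assertingAgents(ds, assertion)
  inits <- vapply(agents, agentInitials, "", ds = ds)
  paste0("! ", paste(plabs, collapse = " AND "), " ! ",
         paste(inits, collapse = " "))
}

## store/refresh the rdfs:label triple of an entity in the default graph
setStoredLabel <- function(ds, iri, label) {
  q <- ds@env$quads
  drop <- is.na(q$graph) & q$s == iri & q$p == RDFS_LABEL
  if (any(drop)) {
    ds@env$quads <- q[!drop, , drop = FALSE]
    ds@env$qkeys <- NULL
  }
  addTriple(ds, iri, RDFS_LABEL, rdfLiteral(label))
  invisible(ds)
}
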