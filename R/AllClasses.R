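#' @import methods
NULL

#' EvidenceDataset: an RDF dataset holding a claim-based evidence record
#'
#' An \code{EvidenceDataset} is an RDF dataset with one default graph and
#' any number of named graphs. The default graph carries the structural
#' record: assertions (claims), the agents making them, the reports and
#' report parts in which they are made, inference and conjunction links
#' between assertions, and labels. Each proposition -- the subject of a
#' claim, \emph{what} is claimed -- is a named graph whose name is the
#' proposition's IRI, so claim subjects are addressable and queryable.
#'
#' The object has reference semantics: builder functions such as
#' \code{\link{makeAssertion}} modify the dataset in place and return the
#' IRI of the entity they created. Use \code{\link{newDataset}} to create
#' one and \code{\link{quads}}, \code{\link{namedGraphs}},
#' \code{\link{prefixes}} to inspect it.
#'
#' @slot env environment holding the quad table, the prefix map, the
#'   resolved vocabulary and the IRI-minting counters.
#' @seealso \code{\link{newDataset}}, \code{\link{serializeDataset}},
#'   \code{\link{validateDataset}}
#' @export
setClass("EvidenceDataset", representation(env = "environment"))

quadColumns <- c("graph", "s", "p", "o", "o_kind", "o_lang", "o_dt")

emptyQuads <- function() {
  data.frame(graph = character(), s = character(), p = character(),
             o = character(), o_kind = character(), o_lang = character(),
             o_dt = character(), stringsAsFactors = FALSE)
}

setValidity("EvidenceDataset", function(object) {
  e <- object@env
  msgs <- character()
  if (!is.data.frame(e$quads) || !identical(names(e$quads), quadColumns))
    msgs <- c(msgs, "quad table is malformed")
  px <- e$prefixes
  if (!is.character(px) || is.null(names(px)))
    msgs <- c(msgs, "prefix map must be a named character vector")
  else if (length(px) && !all(isAbsoluteIri(px)))
    msgs <- c(msgs, "prefix map values must be absolute IRIs")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn EvidenceDataset compact summary: number of triples in the
#'   default graph, number of named graphs, number of assertions.
#' @param object an \code{EvidenceDataset}.
#' @export
setMethod("show", "EvidenceDataset", function(object) {
  q <- object@env$quads
  ng <- unique(q$graph[!is.na(q$graph)])
  voc <- vocabulary(object)
  nAssert <- sum(is.na(q$graph) & q$p == RDF_TYPE & q$o == voc[["assertion"]])
  cat(sprintf(paste0("EvidenceDataset: %d default-graph triple(s), ",
                     "%d named graph(s), %d assertion(s)\n"),
              sum(is.na(q$graph)), length(ng), nAssert))
  invisible(object)
})

#' ClassExpression: structural OWL class expressions
#'
#' A small tree type for the class expressions used to formalize claim
#' subjects: a named class, an existential restriction
#' (\code{property some filler}) or an intersection of expressions.
#' Rendering into Manchester-syntax-flavoured labels is done by
#' \code{\link{renderExpression}}.
#'
#' @slot variant one of \code{"named"}, \code{"some"},
#'   \code{"intersection"}.
#' @slot iri class IRI (named variant).
#' @slot property property IRI (some variant).
#' @slot filler filler expression (some variant) or NULL.
#' @slot operands list of operand expressions (intersection variant).
#' @seealso \code{\link{ceNamed}}, \code{\link{ceSome}},
#'   \code{\link{ceIntersection}}
#' @export
setClass("ClassExpression",
         representation(variant = "character", iri = "character",
                        property = "character", filler = "ANY",
                        operands = "list"))

setValidity("ClassExpression", function(object) {
  v <- object@variant
  if (!v %in% c("named", "some", "intersection"))
    return("variant must be named, some or intersection")
  switch(v,
    named = if (!isAbsoluteIri(object@iri)) "named expression needs a class IRI" else TRUE,
    some = {
      if (!isAbsoluteIri(object@property)) return("some expression needs a property IRI")
      if (!is(object@filler, "ClassExpression")) return("filler must be a ClassExpression")
      TRUE
    },
    intersection = {
      if (length(object@operands) < 2L) return("intersection needs at least 2 operands")
      if (!all(vapply(object@operands, is, logical(1), "ClassExpression")))
        return("intersection operands must be ClassExpressions")
      TRUE
    })
})

#' Construct class expressions
#'
#' @param iri class IRI.
#' @return a \code{\linkS4class{ClassExpression}}.
#' @examples
#' ceIntersection(ceNamed("http://ex.org/A"),
#'                ceSome("http://ex.org/r", ceNamed("http://ex.org/B")))
#' @export
ceNamed <- function(iri) {
  new("ClassExpression", variant = "named", iri = iri,
      property = NA_character_, filler = NULL, operands = list())
}

#' @rdname ceNamed
#' @param property property IRI of an existential restriction.
#' @param filler filler \code{ClassExpression}.
#' @export
ceSome <- function(property, filler) {
  if (is.character(filler)) filler <- ceNamed(filler)
  new("ClassExpression", variant = "some", iri = NA_character_,
      property = property, filler = filler, operands = list())
}

#' @rdname ceNamed
#' @param ... two or more operand expressions (IRIs are promoted to named
#'   expressions).
#' @export
ceIntersection <- function(...) {
  ops <- lapply(list(...), function(x) if (is.character(x)) ceNamed(x) else x)
  new("ClassExpression", variant = "intersection", iri = NA_character_,
      property = NA_character_, filler = NULL, operands = ops)
}

setMethod("show", "ClassExpression", function(object) {
  cat("ClassExpression:", renderExpression(object), "\n")
  invisible(object)
})

#' IndependenceReport: result of the assertion-independence query
#'
#' Answers whether the assertions sharing a given subject proposition
#' pertain to independent observations: they do not when one assertion is
#' (directly or indirectly) inferred from another on the same subject, or
#' when the asserting agent sets overlap.
#'
#' @slot proposition IRI of the shared subject proposition.
#' @slot dependentPairs two-column character matrix; each row is a pair
#'   (dependent assertion, assertion it is inferred from).
#' @slot sharedAgents named list mapping "a|b" unordered assertion pairs
#'   to the character vector of shared agent IRIs (non-empty entries only).
#' @slot independent logical; TRUE iff there are no dependent pairs and no
#'   shared agents.
#' @seealso \code{\link{q3Independence}}
#' @export
setClass("IndependenceReport",
         representation(proposition = "character",
                        dependentPairs = "matrix",
                        sharedAgents = "list",
                        independent = "logical"))

setValidity("IndependenceReport", function(object) {
  ok <- object@independent ==
    (nrow(object@dependentPairs) == 0L && length(object@sharedAgents) == 0L)
  if (!ok) "independent flag inconsistent with pairs/agents" else TRUE
})

setMethod("show", "IndependenceReport", function(object) {
  cat(sprintf("IndependenceReport for <%s>: %s\n", object@proposition,
              if (object@independent) "independent" else "NOT independent"))
  if (nrow(object@dependentPairs))
    for (i in seq_len(nrow(object@dependentPairs)))
      cat(sprintf("  dependent: <%s> inferred from <%s>\n",
                  object@dependentPairs[i, 1], object@dependentPairs[i, 2]))
  for (key in names(object@sharedAgents))
    cat(sprintf("  shared agents (%s): %s\n", key,
                paste(object@sharedAgents[[key]], collapse = ", ")))
  invisible(object)
})
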