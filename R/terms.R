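## RDF term helpers shared across the package.
##
## Terms are plain character strings internally: absolute IRIs, blank nodes
## ("_:" prefix) or, for literal objects, the lexical form accompanied by
## kind/lang/datatype columns in the quad table.

XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"
RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"

RDF_TYPE        <- paste0(RDF_NS, "type")
RDF_FIRST       <- paste0(RDF_NS, "first")
RDF_REST        <- paste0(RDF_NS, "rest")
RDF_NIL         <- paste0(RDF_NS, "nil")
RDFS_LABEL      <- paste0(RDFS_NS, "label")
OWL_CLASS       <- paste0(OWL_NS, "Class")
OWL_RESTRICTION <- paste0(OWL_NS, "Restriction")
OWL_INTERSECTION <- paste0(OWL_NS, "intersectionOf")
OWL_ON_PROPERTY <- paste0(OWL_NS, "onProperty")
OWL_SOME_VALUES <- paste0(OWL_NS, "someValuesFrom")
OWL_OBJECT_PROPERTY <- paste0(OWL_NS, "ObjectProperty")
OWL_THING       <- paste0(OWL_NS, "Thing")
XSD_STRING      <- paste0(XSD_NS, "string")

#' Create an RDF literal
#'
#' Wraps a value so that builder functions treat it as a literal object
#' rather than an IRI. A language tag and a datatype IRI are mutually
#' exclusive, as in RDF 1.1.
#'
#' @param value character scalar, the lexical form.
#' @param lang optional BCP-47 language tag.
#' @param datatype optional datatype IRI; defaults to \code{xsd:string}
#'   when no language tag is given.
#' @return An object of class \code{rdfLiteral}.
#' @examples
#' rdfLiteral("42", datatype = "http://www.w3.org/2001/XMLSchema#integer")
#' rdfLiteral("rat liver", lang = "en")
#' @export
rdfLiteral <- function(value, lang = NULL, datatype = NULL) {
  stopifnot(is.character(value), length(value) == 1L)
  if (!is.null(lang) && !is.null(datatype))
    seeError("BAD_LITERAL", "a literal cannot carry both a language tag and a datatype")
  structure(list(value = value, lang = lang, datatype = datatype),
            class = "rdfLiteral")
}

isLiteral <- function(x) inherits(x, "rdfLiteral")

isBlank <- function(x) startsWith(x, "_:")

#' @export
print.rdfLiteral <- function(x, ...) {
  suffix <- if (!is.null(x$lang)) paste0("@", x$lang)
            else if (!is.null(x$datatype)) paste0("^^<", x$datatype, ">")
            else ""
  cat(sprintf("\"%s\"%s\n", x$value, suffix))
  invisible(x)
}

## Local name of an IRI: the part after the last '#' or '/'.
localName <- function(iri) {
  sub(".*[#/]", "", iri)
}

## Rough absolute-IRI well-formedness check: scheme plus no forbidden chars.
isAbsoluteIri <- function(x) {
  is.character(x) & nzchar(x) &
    grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x) &
    !grepl("[ <>\"{}|\\\\^`]", x)
}

## Signalling helpers: every package error carries a machine-readable code
## as a condition class "semevid_<CODE>".
seeError <- function(code, message, call = sys.call(-1)) {
  stop(errorCondition(sprintf("[%s] %s", code, message),
                      class = c(paste0("semevid_", code), "semevid_error"),
                      call = call))
}

seeAssert <- function(ok, code, message) {
  if (!isTRUE(ok)) seeError(code, message, call = sys.call(-1))
  invisible(TRUE)
}
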