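## Builders for the evidence design patterns: provenance entities,
## subject formalization, assertion creation, reiteration, composition,
## meta-assertion, curator conclusions.
##
## All builders mutate the dataset in place and return the IRI of the
## entity they created. Every builder mints IRIs not previously present.

assertionRoles <- c("conclusion", "factual", "assumption", "terminological",
                    "interpretation", "unspecified")

typeTriple <- function(ds, iri, cls) addTriple(ds, iri, RDF_TYPE, cls)

#' Add provenance entities: agents, reports, report parts
#'
#' Agents are persons (or other role-players) making claims; reports are
#' the accounts (journal articles, database records) in which claims are
#' made; report parts locate claims within a report (e.g. a paragraph)
#' and may be expressed as a text whose verbatim wording is kept via the
#' lexical-structure data property.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param name agent display name, stored as \code{rdfs:label}.
#' @param initials agent initials; uppercase letters only.
#' @param slug optional explicit local name for the minted IRI.
#' @return the IRI of the created entity.
#' @export
addAgent <- function(ds, name, initials, slug = NULL) {
  seeAssert(is.character(initials) && length(initials) == 1L &&
              grepl("^[A-Z]+$", initials),
            "BAD_INITIALS", "initials must be non-empty uppercase letters")
  voc <- vocabulary(ds)
  iri <- mintIri(ds, "agent", slug)
  typeTriple(ds, iri, voc[["agent"]])
  addTriple(ds, iri, RDFS_LABEL, rdfLiteral(name))
  addTriple(ds, iri, voc[["has_initials"]], rdfLiteral(initials))
  iri
}

#' @rdname addAgent
#' @param citation non-empty citation string, stored as the report label.
#' @param url optional URL of the report's digital representation.
#' @export
addReport <- function(ds, citation, url = NULL, slug = NULL) {
  seeAssert(is.character(citation) && length(citation) == 1L && nzchar(citation),
            "EMPTY_CITATION", "report citation must be non-empty")
  voc <- vocabulary(ds)
  iri <- mintIri(ds, "report", slug)
  typeTriple(ds, iri, voc[["report"]])
  addTriple(ds, iri, RDFS_LABEL, rdfLiteral(citation))
  if (!is.null(url))
    addTriple(ds, iri, voc[["has_url"]],
              rdfLiteral(url, datatype = paste0(XSD_NS, "anyURI")))
  iri
}

#' @rdname addAgent
#' @param report IRI of the parent report (must exist in \code{ds}).
#' @param locator human-readable locator, e.g. \code{"paragraph 2"}.
#' @param text optional verbatim text of the part; creates a text entity
#'   linked via \code{is_expressed_as}/\code{has_lexical_structure}.
#' @param lang BCP-47 language tag for \code{text}.
#' @export
addReportPart <- function(ds, report, locator, text = NULL, lang = "en",
                          slug = NULL) {
  voc <- vocabulary(ds)
  q <- quads(ds)
  known <- any(is.na(q$graph) & q$s == report & q$p == RDF_TYPE &
                 q$o == voc[["report"]])
  seeAssert(known, "ORPHAN_PART",
            sprintf("parent report <%s> does not exist in dataset", report))
  iri <- mintIri(ds, "report-part", slug)
  typeTriple(ds, iri, voc[["report_part"]])
  addTriple(ds, iri, RDFS_LABEL, rdfLiteral(locator))
  addTriple(ds, iri, voc[["is_part_of"]], report)
  if (!is.null(text)) {
    seeAssert(nzchar(text), "EMPTY_TEXT", "text must be non-empty")
    tiri <- mintIri(ds, "text", if (is.null(slug)) NULL else paste0(slug, "-text"))
    typeTriple(ds, tiri, voc[["text"]])
    addTriple(ds, tiri, voc[["has_lexical_structure"]],
              rdfLiteral(text, lang = lang))
    addTriple(ds, iri, voc[["is_expressed_as"]], tiri)
  }
  iri
}

#' Declare vocabulary terms for subject formalization
#'
#' Helpers to declare the domain classes, properties and individuals a
#' curator uses inside proposition graphs, with labels that drive the
#' label nomenclature.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param slug local name under the example namespace.
#' @param label \code{rdfs:label}; for properties this is also the text
#'   used when rendering propositions (e.g. \code{"isolated from"}).
#' @return the term's IRI.
#' @export
addClassTerm <- function(ds, slug, label = NULL) {
  iri <- paste0(exNamespace(ds), slug)
  typeTriple(ds, iri, OWL_CLASS)
  if (!is.null(label)) addTriple(ds, iri, RDFS_LABEL, rdfLiteral(label))
  iri
}

#' @rdname addClassTerm
#' @export
addPropertyTerm <- function(ds, slug, label = NULL) {
  iri <- paste0(exNamespace(ds), slug)
  typeTriple(ds, iri, OWL_OBJECT_PROPERTY)
  if (!is.null(label)) addTriple(ds, iri, RDFS_LABEL, rdfLiteral(label))
  iri
}

#' @rdname addClassTerm
#' @param cls optional class IRI the individual is an instance of.
#' @export
addIndividual <- function(ds, slug, label = NULL, cls = NULL) {
  iri <- paste0(exNamespace(ds), slug)
  if (!is.null(cls)) typeTriple(ds, iri, cls)
  if (!is.null(label)) addTriple(ds, iri, RDFS_LABEL, rdfLiteral(label))
  iri
}

## internal: declare a fresh proposition entity for a subject graph
newProposition <- function(ds, triples, slug = NULL, label = NULL) {
  voc <- vocabulary(ds)
  p <- mintIri(ds, "proposition", slug)
  addNamedGraph(ds, p, triples)
  typeTriple(ds, p, voc[["proposition"]])
  lab <- if (is.null(label)) propositionLabel(ds, p) else label
  addTriple(ds, p, RDFS_LABEL, rdfLiteral(lab))
  p
}

#' Formalize claim subjects as proposition graphs
#'
#' Each formalizer mints a fresh proposition whose IRI names a new graph
#' holding the structured subject representation, and labels it from the
#' graph. \code{formalizeType} records an individual's type
#' (\code{individual rdf:type class}); \code{formalizeProperty} a single
#' property triple; \code{formalizeSomeSome} the pattern for statements
#' of the form "some A related to some B": an anonymous individual typed
#' by the intersection of class A and an existential restriction
#' (\code{property some B}), expanded into the OWL 2 RDF mapping triples
#' (\code{owl:intersectionOf} with a two-element RDF list and an
#' \code{owl:Restriction} node).
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param individual,cls IRIs for the type shape.
#' @param label optional label override.
#' @param slug optional explicit proposition local name.
#' @return the new proposition IRI.
#' @examples
#' ds <- newDataset()
#' assay <- addClassTerm(ds, "gamma_ghs_assay", "γ-GHS assay")
#' a1 <- addIndividual(ds, "assay-1", "assay-1")
#' p <- formalizeType(ds, a1, assay)
#' propositionLabel(ds, p)
#' @export
formalizeType <- function(ds, individual, cls, label = NULL, slug = NULL) {
  newProposition(ds, triple(individual, RDF_TYPE, cls), slug, label)
}

#' @rdname formalizeType
#' @param subject,property,object IRIs (or an \code{\link{rdfLiteral}}
#'   object) for the property shape.
#' @export
formalizeProperty <- function(ds, subject, property, object, label = NULL,
                              slug = NULL) {
  newProposition(ds, triple(subject, property, object), slug, label)
}

#' @rdname formalizeType
#' @param classA,classB class IRIs of the existential pattern.
#' @export
formalizeSomeSome <- function(ds, classA, property, classB, label = NULL,
                              slug = NULL) {
  x <- mintBnode(ds); cn <- mintBnode(ds); l1 <- mintBnode(ds)
  l2 <- mintBnode(ds); rn <- mintBnode(ds)
  tr <- rbind(
    triple(x, RDF_TYPE, cn),
    triple(cn, RDF_TYPE, OWL_CLASS),
    triple(cn, OWL_INTERSECTION, l1),
    triple(l1, RDF_FIRST, classA),
    triple(l1, RDF_REST, l2),
    triple(l2, RDF_FIRST, rn),
    triple(l2, RDF_REST, RDF_NIL),
    triple(rn, RDF_TYPE, OWL_RESTRICTION),
    triple(rn, OWL_ON_PROPERTY, property),
    triple(rn, OWL_SOME_VALUES, classB))
  newProposition(ds, tr, slug, label)
}

#' Create an assertion
#'
#' An assertion is a claim made by particular agents on a particular
#' occasion that its subject proposition(s) hold. The default graph gains
#' \code{asserts} and \code{is_assertion_made_by} triples, plus
#' \code{is_assertion_made_in} when a report part (or report) is given;
#' curator claims typically carry no report link. The assertion label is
#' computed from the proposition labels and agent initials; the optional
#' role is stored as a dataset-local annotation.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param propositions character vector (ordered, length >= 1) of
#'   proposition IRIs.
#' @param agents character vector (ordered, length >= 1) of agent IRIs.
#' @param reportPart optional report-part (or report) IRI.
#' @param role one of \code{"conclusion"}, \code{"factual"},
#'   \code{"assumption"}, \code{"terminological"},
#'   \code{"interpretation"}, \code{"unspecified"}.
#' @param slug optional explicit local name.
#' @return the new assertion IRI.
#' @export
makeAssertion <- function(ds, propositions, agents, reportPart = NULL,
                          role = "unspecified", slug = NULL) {
  if (!length(propositions)) seeError("NO_SUBJECT", "an assertion needs at least one proposition")
  if (!length(agents)) seeError("NO_AGENT", "an assertion needs at least one agent")
  seeAssert(role %in% assertionRoles, "BAD_ROLE",
            paste("role must be one of:", paste(assertionRoles, collapse = ", ")))
  voc <- vocabulary(ds)
  a <- mintIri(ds, "assertion", slug)
  typeTriple(ds, a, voc[["assertion"]])
  for (p in propositions) addTriple(ds, a, voc[["asserts"]], p)
  for (g in agents) addTriple(ds, a, voc[["is_assertion_made_by"]], g)
  if (!is.null(reportPart))
    addTriple(ds, a, voc[["is_assertion_made_in"]], reportPart)
  if (role != "unspecified")
    addTriple(ds, a, voc[["has_role"]], rdfLiteral(role))
  setStoredLabel(ds, a, assertionLabel(ds, a))
  a
}

assertionExists <- function(ds, a) {
  q <- quads(ds)
  voc <- vocabulary(ds)
  any(is.na(q$graph) & q$s == a & q$p == RDF_TYPE & q$o == voc[["assertion"]])
}

requireAssertion <- function(ds, a) {
  seeAssert(assertionExists(ds, a), "UNKNOWN_ASSERTION",
            sprintf("<%s> is not an assertion in this dataset", a))
}

#' Reiterate a previous finding
#'
#' A claim repeating a previous finding is a new assertion on the
#' \emph{same} proposition instance(s) as the source, linked to the
#' source via \code{is_directly_inferred_from}.
#'
#' @inheritParams makeAssertion
#' @param source IRI of the assertion being reiterated.
#' @return the new assertion IRI.
#' @export
reiterate <- function(ds, source, agents, reportPart = NULL, slug = NULL) {
  requireAssertion(ds, source)
  props <- assertedPropositions(ds, source)
  a <- makeAssertion(ds, props, agents, reportPart, slug = slug)
  linkInference(ds, a, source)
  a
}

#' Compose assertions into a composite assertion
#'
#' When a conclusion is inferred from several premises jointly, the
#' premises are linked by \code{has_conjunctive_part} to one composite
#' assertion, which is then used as the single premise. The composite's
#' subject list is the concatenation of its parts' propositions, its
#' agents the union of the parts' agents, and its label joins the part
#' proposition labels with \code{" AND "}.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param parts character vector (length >= 2, distinct) of assertion IRIs.
#' @param slug optional explicit local name.
#' @return the composite assertion IRI.
#' @export
composeAssertions <- function(ds, parts, slug = NULL) {
  seeAssert(length(parts) >= 2L, "TOO_FEW_PARTS",
            "a composite assertion needs at least two parts")
  seeAssert(!anyDuplicated(parts), "DUPLICATE_PART",
            "composite parts must be distinct")
  for (p in parts) requireAssertion(ds, p)
  voc <- vocabulary(ds)
  props <- unlist(lapply(parts, assertedPropositions, ds = ds), use.names = FALSE)
  agents <- unique(unlist(lapply(parts, assertingAgents, ds = ds), use.names = FALSE))
  comp <- mintIri(ds, "composite", slug)
  typeTriple(ds, comp, voc[["assertion"]])
  for (p in props) addTriple(ds, comp, voc[["asserts"]], p)
  for (g in agents) addTriple(ds, comp, voc[["is_assertion_made_by"]], g)
  for (p in parts) addTriple(ds, comp, voc[["has_conjunctive_part"]], p)
  setStoredLabel(ds, comp, assertionLabel(ds, comp))
  comp
}

#' Link a conclusion to a premise
#'
#' Adds \code{is_directly_inferred_from(conclusion, premise)} to the
#' default graph. Idempotent (set semantics); self-links are rejected.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param conclusion,premise assertion IRIs.
#' @return the dataset, invisibly.
#' @export
linkInference <- function(ds, conclusion, premise) {
  requireAssertion(ds, conclusion)
  requireAssertion(ds, premise)
  if (identical(conclusion, premise))
    seeError("SELF_INFERENCE", "an assertion cannot be inferred from itself")
  voc <- vocabulary(ds)
  addTriple(ds, conclusion, voc[["is_directly_inferred_from"]], premise)
  invisible(ds)
}

#' Formalize an attribution: a proposition about another assertion
#'
#' Creates a proposition whose graph states that \code{about} was made in
#' \code{report} -- a named graph referencing another assertion, which is
#' the mechanism for consecutive layers of interpretation (a curator
#' asserting \emph{that} authors assert something). Meta-assertions over
#' such propositions can themselves be meta-asserted, to arbitrary depth.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param about IRI of the assertion the proposition is about.
#' @param report report (or report part) IRI it is attributed to.
#' @param slug optional explicit proposition local name.
#' @return the new proposition IRI.
#' @export
formalizeAttribution <- function(ds, about, report, slug = NULL) {
  requireAssertion(ds, about)
  voc <- vocabulary(ds)
  newProposition(ds, triple(about, voc[["is_assertion_made_in"]], report), slug)
}

#' Curator conclusions: from an author statement or from the evidence
#'
#' Two semantically different patterns for appending a third party's own
#' conclusions. \code{concludeFromStatement} bases the new claim on the
#' author statement itself: the curator assertion shares the author
#' assertion's proposition(s) and is directly inferred from it, without
#' affirming how the authors reached it. \code{concludeFromEvidence}
#' affirms a conclusion on the basis of reported evidence: the curator
#' assertion asserts the given proposition(s) and is inferred from the
#' given premises (a fresh composite is built when there are several),
#' leaving the authors' own conclusion out of the inference trail.
#' Both tag the new assertion with role \code{"interpretation"}.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param authorAssertion assertion IRI the conclusion is drawn from.
#' @param agent IRI of the concluding agent.
#' @param slug optional explicit local name.
#' @return the new assertion IRI.
#' @export
concludeFromStatement <- function(ds, authorAssertion, agent, slug = NULL) {
  requireAssertion(ds, authorAssertion)
  props <- assertedPropositions(ds, authorAssertion)
  a <- makeAssertion(ds, props, agent, role = "interpretation", slug = slug)
  linkInference(ds, a, authorAssertion)
  a
}

#' @rdname concludeFromStatement
#' @param propositions proposition IRI(s) the curator asserts.
#' @param premises non-empty character vector of premise assertion IRIs.
#' @export
concludeFromEvidence <- function(ds, propositions, agent, premises,
                                 slug = NULL) {
  seeAssert(length(premises) >= 1L, "NO_PREMISE",
            "concludeFromEvidence needs at least one premise")
  for (p in premises) requireAssertion(ds, p)
  a <- makeAssertion(ds, propositions, agent, role = "interpretation",
                     slug = slug)
  if (length(premises) >= 2L) {
    comp <- composeAssertions(ds, premises)
    linkInference(ds, a, comp)
  } else {
    linkInference(ds, a, premises[[1]])
  }
  a
}
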