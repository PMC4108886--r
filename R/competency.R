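## Competency questions over an evidence dataset, with equivalent
## SPARQL 1.1 emission.
##
## Each question has a programmatic implementation and a SPARQL SELECT
## rendering (emitSparql) that returns the same answers when executed by
## a SPARQL engine over the TriG serialization; the agreement of the two
## routes is the central cross-check of the query layer.

## reports of one assertion (via its made_in target)
reportsOfAssertion <- function(ds, a) {
  q <- quads(ds)
  voc <- vocabulary(ds)
  dft <- is.na(q$graph)
  made <- q$o[dft & q$s == a & q$p == voc[["is_assertion_made_in"]]]
  out <- character(0)
  for (m in made) out <- c(out, resolveProvenance(ds, m)$report)
  unique(out)
}

## assertions whose subject graph matches the existential pattern for
## (entityClass, relation); returns data.frame(assertion, proposition,
## filler)
matchLocationPattern <- function(ds, entityClass, relation) {
  q <- quads(ds)
  voc <- vocabulary(ds)
  dft <- is.na(q$graph)
  am <- q[dft & q$p == voc[["asserts"]], c("s", "o")]
  rows <- list()
  for (p in unique(am$o)) {
    if (!(p %in% namedGraphs(ds))) next
    ss <- matchSomeSome(namedGraph(ds, p))
    if (is.null(ss) || ss$classA != entityClass || ss$property != relation) next
    for (a in am$s[am$o == p])
      rows[[length(rows) + 1L]] <- data.frame(assertion = a, proposition = p,
                                              filler = ss$classB,
                                              stringsAsFactors = FALSE)
  }
  if (!length(rows)) data.frame(assertion = character(), proposition = character(),
                                filler = character(), stringsAsFactors = FALSE)
  else do.call(rbind, rows)
}

#' Q1: which locations of an entity have been asserted?
#'
#' Scans every asserted proposition graph for the existential pattern
#' "(entityClass and relation some X)" and returns the filler classes X.
#' Matching is structural over the OWL 2 RDF mapping triples; no subclass
#' reasoning over the entity class is performed.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param entityClass class IRI of the entity (e.g. the GS-enzyme class).
#' @param relation property IRI of the locating relation (e.g.
#'   is-isolated-from).
#' @return sorted character vector of filler class IRIs.
#' @export
q1Locations <- function(ds, entityClass, relation) {
  sort(unique(matchLocationPattern(ds, entityClass, relation)$filler))
}

#' Q2: where (in which reports) has the located entity been reported?
#'
#' Reports, via report parts, of all assertions matched by the Q1
#' pattern.
#'
#' @inheritParams q1Locations
#' @return sorted character vector of report IRIs.
#' @export
q2Reports <- function(ds, entityClass, relation) {
  hits <- matchLocationPattern(ds, entityClass, relation)
  sort(unique(unlist(lapply(unique(hits$assertion), reportsOfAssertion, ds = ds),
                     use.names = FALSE)))
}

#' Q3: do assertions on a subject pertain to independent observations?
#'
#' Assertions sharing the proposition are pairwise checked for
#' argumentative dependency (one in the other's premises closure) and
#' for shared asserting agents. The observations are independent only
#' when neither occurs.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param proposition IRI of the shared subject proposition.
#' @return an \code{\linkS4class{IndependenceReport}}.
#' @export
q3Independence <- function(ds, proposition) {
  as <- assertionsOnSubject(ds, proposition)
  pairs <- matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("dependent", "premise")))
  shared <- list()
  if (length(as) > 1L) {
    closures <- lapply(as, premisesClosure, ds = ds)
    names(closures) <- as
    for (i in seq_along(as)) for (j in seq_along(as)) {
      if (i == j) next
      if (as[j] %in% closures[[as[i]]])
        pairs <- rbind(pairs, c(as[i], as[j]))
    }
    for (i in seq_along(as)) for (j in seq_along(as)) {
      if (i >= j) next
      common <- intersect(assertingAgents(ds, as[i]), assertingAgents(ds, as[j]))
      if (length(common))
        shared[[paste(as[i], as[j], sep = "|")]] <- sort(common)
    }
  }
  new("IndependenceReport", proposition = proposition,
      dependentPairs = pairs, sharedAgents = shared,
      independent = nrow(pairs) == 0L && length(shared) == 0L)
}

## types of an IRI gathered from every graph (default and named)
typesOf <- function(ds, iri) {
  q <- quads(ds)
  unique(q$o[q$s == iri & q$p == RDF_TYPE & q$o_kind == "iri"])
}

## IRIs mentioned (as subject or object) in a proposition graph
mentionedIris <- function(ds, p) {
  tr <- namedGraph(ds, p)
  unique(c(tr$s[!isBlank(tr$s)], tr$o[tr$o_kind == "iri"]))
}

#' Q4: is there experimental evidence, and where is it described?
#'
#' Returns the reports of assertions in the premises closure whose
#' subject graph mentions an individual typed (anywhere in the dataset)
#' by one of the designated experimental-process classes. Which classes
#' count as experimental is the caller's domain knowledge, hence the
#' configurable set.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param assertion assertion IRI whose evidence is examined.
#' @param experimentalClasses character vector of experimental-process
#'   class IRIs; defaults to the assay and purification classes of the
#'   case-study vocabulary.
#' @return sorted character vector of report IRIs.
#' @export
q4ExperimentalEvidence <- function(ds, assertion,
                                   experimentalClasses = gsExperimentalClasses(ds)) {
  requireAssertion(ds, assertion)
  cl <- premisesClosure(ds, assertion)
  out <- character(0)
  for (b in cl) {
    props <- assertedPropositions(ds, b)
    props <- props[props %in% namedGraphs(ds)]
    mentioned <- unique(unlist(lapply(props, mentionedIris, ds = ds),
                               use.names = FALSE))
    typed <- any(vapply(mentioned, function(i)
      length(intersect(typesOf(ds, i), experimentalClasses)) > 0L, logical(1)))
    if (isTRUE(typed)) out <- c(out, reportsOfAssertion(ds, b))
  }
  sort(unique(out))
}

roleOf <- function(ds, a) {
  q <- quads(ds)
  voc <- vocabulary(ds)
  hit <- is.na(q$graph) & q$s == a & q$p == voc[["has_role"]]
  if (any(hit)) q$o[hit][1] else "unspecified"
}

#' Q5: which observations and techniques established the finding?
#'
#' Locates, within the assertion's premises closure, the technique
#' assertions -- subject graphs typing an experimental-process individual
#' with one of the designated classes -- and pairs each technique with
#' the observation it grounds: the nearest assertion in the conclusion
#' direction tagged with role \code{"conclusion"} (no other
#' conclusion-role assertion strictly between).
#'
#' @inheritParams q4ExperimentalEvidence
#' @return data frame with columns \code{observation} (proposition IRI),
#'   \code{technique} (class IRI), \code{observationAssertion},
#'   \code{techniqueAssertion}.
#' @export
q5Techniques <- function(ds, assertion,
                         experimentalClasses = gsExperimentalClasses(ds)) {
  requireAssertion(ds, assertion)
  cl <- premisesClosure(ds, assertion)
  scope <- c(assertion, cl)
  empty <- data.frame(observation = character(), technique = character(),
                      observationAssertion = character(),
                      techniqueAssertion = character(), stringsAsFactors = FALSE)
  rows <- list(empty)
  closures <- lapply(scope, premisesClosure, ds = ds)
  names(closures) <- scope
  conclusionNodes <- scope[vapply(scope, roleOf, "", ds = ds) == "conclusion"]
  for (t in cl) {
    props <- assertedPropositions(ds, t)
    props <- props[props %in% namedGraphs(ds)]
    for (p in props) {
      tr <- namedGraph(ds, p)
      hit <- tr$p == RDF_TYPE & tr$o_kind == "iri" & tr$o %in% experimentalClasses
      if (!any(hit)) next
      anc <- conclusionNodes[vapply(conclusionNodes, function(x)
        t %in% closures[[x]], logical(1))]
      nearest <- anc[vapply(anc, function(x) {
        mids <- intersect(anc, closures[[x]])
        !any(vapply(mids, function(m) t %in% closures[[m]], logical(1)))
      }, logical(1))]
      for (tc in unique(tr$o[hit])) for (obs in nearest) {
        for (op in assertedPropositions(ds, obs))
          rows[[length(rows) + 1L]] <-
            data.frame(observation = op, technique = tc,
                       observationAssertion = obs, techniqueAssertion = t,
                       stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  res <- res[!duplicated(res), , drop = FALSE]
  res[order(res$observation, res$technique), , drop = FALSE]
}

#' Q6: who created this account of the findings?
#'
#' Returns the agents of meta-assertions: assertions whose subject graph
#' references (as subject or object of a triple) a member of the given
#' assertion set -- e.g. a curator's claim that the authors made these
#' assertions in their report.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @param assertions character vector of assertion IRIs the account is
#'   about.
#' @return sorted character vector of agent IRIs.
#' @export
q6AccountCreator <- function(ds, assertions) {
  q <- quads(ds)
  voc <- vocabulary(ds)
  dft <- is.na(q$graph)
  metas <- unique(q$s[dft & q$p == voc[["asserts"]]])
  out <- character(0)
  for (m in metas) {
    props <- assertedPropositions(ds, m)
    props <- props[props %in% namedGraphs(ds)]
    touches <- any(vapply(props, function(p)
      length(intersect(mentionedIris(ds, p), assertions)) > 0L, logical(1)))
    if (isTRUE(touches)) out <- c(out, assertingAgents(ds, m))
  }
  sort(unique(out))
}

## ---- SPARQL emission -------------------------------------------------

sparqlIri <- function(x) paste0("<", x, ">")

sparqlValues <- function(var, iris) {
  sprintf("  VALUES %s { %s }", var, paste(sparqlIri(iris), collapse = " "))
}

#' Emit SPARQL 1.1 for a competency question
#'
#' Renders the question as an executable SPARQL 1.1 SELECT over the TriG
#' dataset (GRAPH patterns address proposition graphs; property paths
#' traverse the composite-expanded premise relation). Running the text
#' with a SPARQL engine on \code{\link{serializeDataset}} output returns
#' the same answers as the programmatic functions.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}} (supplies the
#'   vocabulary IRIs).
#' @param qid one of \code{"Q1"} ... \code{"Q6"}.
#' @param entityClass,relation bindings for Q1/Q2.
#' @param proposition binding for Q3.
#' @param assertion binding for Q4/Q5.
#' @param experimentalClasses bindings for Q4/Q5.
#' @param assertions bindings for Q6.
#' @return SPARQL query text (character scalar).
#' @export
emitSparql <- function(ds, qid, entityClass = NULL, relation = NULL,
                       proposition = NULL, assertion = NULL,
                       experimentalClasses = NULL, assertions = NULL) {
  seeAssert(qid %in% paste0("Q", 1:6), "UNKNOWN_QUERY",
            "qid must be one of Q1..Q6")
  voc <- vocabulary(ds)
  E <- sprintf("(%s/%s?)", sparqlIri(voc[["is_directly_inferred_from"]]),
               sparqlIri(voc[["has_conjunctive_part"]]))
  prologue <- paste0(
    "PREFIX rdf: <", RDF_NS, ">\n",
    "PREFIX owl: <", OWL_NS, ">\n")
  locationPattern <- function() {
    paste(
      sprintf("  ?a rdf:type %s .", sparqlIri(voc[["assertion"]])),
      sprintf("  ?a %s ?p .", sparqlIri(voc[["asserts"]])),
      "  GRAPH ?p {",
      "    ?x rdf:type ?c .",
      "    ?c owl:intersectionOf ?l1 .",
      sprintf("    ?l1 rdf:first %s ;", sparqlIri(entityClass)),
      "        rdf:rest ?l2 .",
      "    ?l2 rdf:first ?r .",
      sprintf("    ?r owl:onProperty %s ;", sparqlIri(relation)),
      "       owl:someValuesFrom ?location .",
      "  }", sep = "\n")
  }
  reportJoin <- function(avar) {
    paste(
      sprintf("  %s %s ?src .", avar, sparqlIri(voc[["is_assertion_made_in"]])),
      sprintf("  OPTIONAL { ?src %s ?parent . }", sparqlIri(voc[["is_part_of"]])),
      "  BIND(COALESCE(?parent, ?src) AS ?report)",
      sprintf("  ?report rdf:type %s .", sparqlIri(voc[["report"]])),
      sep = "\n")
  }
  body <- switch(qid,
    Q1 = {
      seeAssert(!is.null(entityClass) && !is.null(relation), "MISSING_BINDING",
                "Q1 needs entityClass and relation")
      paste("SELECT DISTINCT ?location WHERE {", locationPattern(), "}", sep = "\n")
    },
    Q2 = {
      seeAssert(!is.null(entityClass) && !is.null(relation), "MISSING_BINDING",
                "Q2 needs entityClass and relation")
      paste("SELECT DISTINCT ?report WHERE {", locationPattern(),
            reportJoin("?a"), "}", sep = "\n")
    },
    Q3 = {
      seeAssert(!is.null(proposition), "MISSING_BINDING", "Q3 needs proposition")
      paste("SELECT DISTINCT ?a1 ?a2 WHERE {",
            sparqlValues("?p", proposition),
            sprintf("  ?a1 %s ?p .", sparqlIri(voc[["asserts"]])),
            sprintf("  ?a2 %s ?p .", sparqlIri(voc[["asserts"]])),
            "  FILTER(?a1 != ?a2)",
            sprintf("  ?a1 %s+ ?a2 .", E),
            "}", sep = "\n")
    },
    Q4 = {
      seeAssert(!is.null(assertion) && length(experimentalClasses) > 0L,
                "MISSING_BINDING", "Q4 needs assertion and experimentalClasses")
      paste("SELECT DISTINCT ?report WHERE {",
            sparqlValues("?tc", experimentalClasses),
            sprintf("  %s %s+ ?b .", sparqlIri(assertion), E),
            sprintf("  ?b %s ?p .", sparqlIri(voc[["asserts"]])),
            "  { GRAPH ?p { ?i ?pp ?oo . } } UNION { GRAPH ?p { ?ss ?pp ?i . } }",
            "  FILTER(isIRI(?i))",
            "  { ?i rdf:type ?tc . } UNION { GRAPH ?g2 { ?i rdf:type ?tc . } }",
            reportJoin("?b"), "}", sep = "\n")
    },
    Q5 = {
      seeAssert(!is.null(assertion) && length(experimentalClasses) > 0L,
                "MISSING_BINDING", "Q5 needs assertion and experimentalClasses")
      paste("SELECT DISTINCT ?observation ?tc WHERE {",
            sparqlValues("?tc", experimentalClasses),
            sprintf("  %s %s* ?obs .", sparqlIri(assertion), E),
            sprintf("  ?obs %s+ ?t .", E),
            sprintf("  ?t %s ?tp .", sparqlIri(voc[["asserts"]])),
            "  GRAPH ?tp { ?i rdf:type ?tc . }",
            sprintf("  ?obs %s \"conclusion\" .", sparqlIri(voc[["has_role"]])),
            sprintf("  ?obs %s ?observation .", sparqlIri(voc[["asserts"]])),
            "  FILTER NOT EXISTS {",
            sprintf("    ?obs %s+ ?mid .", E),
            sprintf("    ?mid %s+ ?t .", E),
            sprintf("    ?mid %s \"conclusion\" .", sparqlIri(voc[["has_role"]])),
            "  }",
            "}", sep = "\n")
    },
    Q6 = {
      seeAssert(length(assertions) > 0L, "MISSING_BINDING", "Q6 needs assertions")
      paste("SELECT DISTINCT ?agent WHERE {",
            sparqlValues("?target", assertions),
            sprintf("  ?m rdf:type %s .", sparqlIri(voc[["assertion"]])),
            sprintf("  ?m %s ?p .", sparqlIri(voc[["asserts"]])),
            sprintf("  ?m %s ?agent .", sparqlIri(voc[["is_assertion_made_by"]])),
            "  { GRAPH ?p { ?target ?pp ?oo . } } UNION { GRAPH ?p { ?ss ?pp ?target . } }",
            "}", sep = "\n")
    })
  paste0(prologue, body, "\n")
}
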