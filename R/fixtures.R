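## Programmatic reconstruction of the glutamine-synthetase (GS)
## localisation case study: the evidence, reported across two articles,
## that the enzyme GS (EC 6.3.1.2) was isolated from rat liver.
##
## A 1985 review asserts (A1) that GS was isolated from rat liver,
## reiterating the principal conclusion (A2) of a 1972 primary report in
## which a protein sample was extracted from rat livers (TLM
## purification), assayed for gamma-glutamyl hydroxamate synthesis
## (gamma-GHS assay) and thereby shown to carry GS activity. The
## argumentative chain A1 <- A2 <- (A3,A4,A5); A3 <- (A6,A7,A8);
## A8 <- (A9..A12); A5 <- (A15..A20) is built with the package's
## builders, along with a curator meta-assertion, the two curator
## conclusion patterns (from statement / from evidence) and an
## alternative interpretation reading the same data as evidence for
## gamma-glutamyl transferase (GGT, EC 2.3.2.2).
##
## The A15-A20 justification trail of A5 and the internal structure of
## the alternative-interpretation chain A40-A46 are reconstructions by
## symmetry with the fully described A6-A12 chain; the report-part texts
## are illustrative stand-ins, not quotations.

gsVocabularySlugs <- list(
  classes = c(gs_enzyme = "GS-enzyme",
              gs_activity = "GS-activity",
              rat_liver = "rat liver",
              biological_sample = "biological sample",
              gamma_ghs_assay = "γ-GHS assay",
              ggt_enzyme = "GGT-enzyme",
              ggt_activity = "GGT-activity",
              tlm_purification = "TLM purification",
              data_item = "data item",
              gs_activity_measurement = "GS-activity measurement",
              ggt_activity_measurement = "GGT-activity measurement",
              protein_isolation = "protein isolation"),
  properties = c(is_isolated_from = "isolated from",
                 has_quality = "has",
                 is_input_to = "input to",
                 has_output = "has output",
                 is_output_of = "output of",
                 is_measurement_of = "measurement of",
                 achieves_objective = "achieves objective",
                 is_borne_by = "borne by",
                 determines = "determines"))

#' Experimental-process classes of the case-study vocabulary
#'
#' Default value of the configurable experimental-class set used by
#' \code{\link{q4ExperimentalEvidence}} and \code{\link{q5Techniques}}:
#' the assay and purification process classes.
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}} (supplies the
#'   example namespace).
#' @return character vector of class IRIs.
#' @export
gsExperimentalClasses <- function(ds) {
  paste0(exNamespace(ds), c("gamma_ghs_assay", "tlm_purification"))
}

#' Default query bindings for the case study
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @return list with \code{entityClass} (the GS-enzyme class IRI) and
#'   \code{relation} (the isolated-from property IRI).
#' @export
gsQueryDefaults <- function(ds) {
  ns <- exNamespace(ds)
  list(entityClass = paste0(ns, "gs_enzyme"),
       relation = paste0(ns, "is_isolated_from"))
}

#' Build the glutamine-synthetase case-study fixture
#'
#' Reconstructs the GS evidence record programmatically. Variants:
#' \describe{
#'   \item{base}{agents, reports and the argumentative chain A1--A12,
#'     A15--A20 with its composites, plus the curator meta-assertion
#'     attributing A10 to the 1972 report.}
#'   \item{pattern1}{base plus a curator conclusion A30 drawn from the
#'     authors' statement A2 itself.}
#'   \item{pattern2}{base plus curator conclusions A31/A32 affirming the
#'     reported data and procedures, composed (with the terminological
#'     assertion A4) into the premise of A30 -- leaving the authors' own
#'     conclusion A2 out of the inference trail.}
#'   \item{alternative}{base plus the alternative interpretation
#'     A40--A46 reading the same data as evidence that GGT-enzyme was
#'     isolated from rat liver.}
#'   \item{full}{the union of all of the above.}
#' }
#'
#' @param variant one of \code{"base"}, \code{"pattern1"},
#'   \code{"pattern2"}, \code{"alternative"}, \code{"full"}.
#' @return list with elements \code{dataset}
#'   (\code{\linkS4class{EvidenceDataset}}) and \code{ids} (named
#'   character vector of the well-known IRIs: agents \code{AM}, \code{ST},
#'   \code{JL}, \code{CB}; reports; assertions \code{A1}...; composites
#'   \code{c1}...; propositions \code{p1}...).
#' @examples
#' fx <- buildGsCaseStudy("base")
#' assertionLabel(fx$dataset, fx$ids[["A1"]])
#' @export
buildGsCaseStudy <- function(variant = c("base", "pattern1", "pattern2",
                                         "alternative", "full")) {
  variant <- match.arg(variant)
  ds <- newDataset()
  ids <- character(0)
  keep <- function(key, iri) { ids[key] <<- iri; iri }

  for (slug in names(gsVocabularySlugs$classes))
    addClassTerm(ds, slug, gsVocabularySlugs$classes[[slug]])
  for (slug in names(gsVocabularySlugs$properties))
    addPropertyTerm(ds, slug, gsVocabularySlugs$properties[[slug]])
  ns <- exNamespace(ds)
  cls <- function(x) paste0(ns, x)

  sample1 <- addIndividual(ds, "sample-1", "sample-1", cls("biological_sample"))
  assay1 <- addIndividual(ds, "assay-1", "assay-1")
  dataItem1 <- addIndividual(ds, "data-item-1", "data item 1", cls("data_item"))
  purification1 <- addIndividual(ds, "purification-1", "purification-1")
  livers1 <- addIndividual(ds, "livers-1", "livers-1")

  AM <- keep("AM", addAgent(ds, "A. Meister", "AM", slug = "meister"))
  ST <- keep("ST", addAgent(ds, "S. Tate", "ST", slug = "tate"))
  JL <- keep("JL", addAgent(ds, "J. Leu", "JL", slug = "leu"))
  CB <- keep("CB", addAgent(ds, "C. Bölling", "CB", slug = "boelling"))
  tateAgents <- c(ST, JL, AM)

  meister1985 <- keep("meister1985",
    addReport(ds, "Meister 1985", url = "https://example.org/meister-1985",
              slug = "meister-1985"))
  tate1972 <- keep("tate1972",
    addReport(ds, "Tate 1972", url = "https://example.org/tate-1972",
              slug = "tate-1972"))
  meisterPart <- keep("meisterPart",
    addReportPart(ds, meister1985, "paragraph 2",
                  text = "Glutamine synthetase has been isolated from rat liver.",
                  slug = "meister-1985-paragraph-2"))
  tatePart <- keep("tatePart",
    addReportPart(ds, tate1972, "results section",
                  text = paste("A protein sample purified from rat livers showed",
                               "γ-glutamyl hydroxamate synthesis activity."),
                  slug = "tate-1972-results"))

  ## -- principal chain -------------------------------------------------
  p1 <- keep("p1", formalizeSomeSome(ds, cls("gs_enzyme"), cls("is_isolated_from"),
                                     cls("rat_liver"), slug = "proposition-1"))
  A2 <- keep("A2", makeAssertion(ds, p1, tateAgents, tatePart,
                                 role = "conclusion", slug = "A2"))
  A1 <- keep("A1", reiterate(ds, A2, AM, meisterPart, slug = "A1"))

  p3 <- keep("p3", formalizeProperty(ds, sample1, cls("has_quality"),
                                     cls("gs_activity")))
  A3 <- keep("A3", makeAssertion(ds, p3, tateAgents, tatePart,
                                 role = "conclusion", slug = "A3"))
  p4 <- keep("p4", formalizeProperty(ds, cls("gs_activity"), cls("is_borne_by"),
                                     cls("gs_enzyme")))
  A4 <- keep("A4", makeAssertion(ds, p4, tateAgents, tatePart,
                                 role = "terminological", slug = "A4"))
  p5 <- keep("p5", formalizeProperty(ds, sample1, cls("is_isolated_from"),
                                     cls("rat_liver")))
  A5 <- keep("A5", makeAssertion(ds, p5, tateAgents, tatePart,
                                 role = "conclusion", slug = "A5"))
  c1 <- keep("c1", composeAssertions(ds, c(A3, A4, A5), slug = "composite-A3-A5"))
  linkInference(ds, A2, c1)

  A6 <- keep("A6", makeAssertion(ds,
    keep("p6", formalizeProperty(ds, sample1, cls("is_input_to"), assay1)),
    tateAgents, tatePart, slug = "A6"))
  A7 <- keep("A7", makeAssertion(ds,
    keep("p7", formalizeProperty(ds, assay1, cls("has_output"), dataItem1)),
    tateAgents, tatePart, slug = "A7"))
  A8 <- keep("A8", makeAssertion(ds,
    keep("p8", formalizeProperty(ds, dataItem1, cls("is_measurement_of"),
                                 cls("gs_activity"))),
    tateAgents, tatePart, slug = "A8"))
  c2 <- keep("c2", composeAssertions(ds, c(A6, A7, A8), slug = "composite-A6-A8"))
  linkInference(ds, A3, c2)

  A9 <- keep("A9", makeAssertion(ds,
    keep("p9", formalizeProperty(ds, dataItem1, cls("is_output_of"), assay1)),
    tateAgents, tatePart, role = "factual", slug = "A9"))
  A10 <- keep("A10", makeAssertion(ds,
    keep("p10", formalizeType(ds, assay1, cls("gamma_ghs_assay"))),
    tateAgents, tatePart, role = "factual", slug = "A10"))
  A11 <- keep("A11", makeAssertion(ds,
    keep("p11", formalizeProperty(ds, assay1, cls("achieves_objective"),
                                  cls("gs_activity_measurement"))),
    tateAgents, tatePart, role = "assumption", slug = "A11"))
  A12 <- keep("A12", makeAssertion(ds,
    keep("p12", formalizeProperty(ds, cls("gs_activity_measurement"),
                                  cls("determines"), cls("gs_activity"))),
    tateAgents, tatePart, role = "terminological", slug = "A12"))
  c3 <- keep("c3", composeAssertions(ds, c(A9, A10, A11, A12),
                                     slug = "composite-A9-A12"))
  linkInference(ds, A8, c3)

  ## -- justification trail of A5 (reconstructed by symmetry) ------------
  A15 <- keep("A15", makeAssertion(ds,
    keep("p15", formalizeProperty(ds, sample1, cls("is_output_of"), purification1)),
    tateAgents, tatePart, role = "factual", slug = "A15"))
  A16 <- keep("A16", makeAssertion(ds,
    keep("p16", formalizeProperty(ds, livers1, cls("is_input_to"), purification1)),
    tateAgents, tatePart, role = "factual", slug = "A16"))
  A17 <- keep("A17", makeAssertion(ds,
    keep("p17", formalizeType(ds, livers1, cls("rat_liver"))),
    tateAgents, tatePart, role = "factual", slug = "A17"))
  A18 <- keep("A18", makeAssertion(ds,
    keep("p18", formalizeType(ds, purification1, cls("tlm_purification"))),
    tateAgents, tatePart, role = "factual", slug = "A18"))
  A19 <- keep("A19", makeAssertion(ds,
    keep("p19", formalizeProperty(ds, purification1, cls("achieves_objective"),
                                  cls("protein_isolation"))),
    tateAgents, tatePart, role = "assumption", slug = "A19"))
  A20 <- keep("A20", makeAssertion(ds,
    keep("p20", formalizeProperty(ds, cls("protein_isolation"), cls("determines"),
                                  cls("biological_sample"))),
    tateAgents, tatePart, role = "terminological", slug = "A20"))
  c4 <- keep("c4", composeAssertions(ds, c(A15, A16, A17, A18, A19, A20),
                                     slug = "composite-A15-A20"))
  linkInference(ds, A5, c4)

  ## -- curator meta-assertion: 'A10 was made in the 1972 report' --------
  pM <- keep("pM", formalizeAttribution(ds, A10, tate1972,
                                        slug = "proposition-meta-A10"))
  keep("M1", makeAssertion(ds, pM, CB, slug = "M1"))

  ## -- curator conclusion patterns --------------------------------------
  both <- variant == "full"
  if (variant %in% c("pattern1", "full")) {
    keep(if (both) "A30.statement" else "A30",
         concludeFromStatement(ds, A2, CB,
                               slug = if (both) "A30-statement" else "A30"))
  }
  if (variant %in% c("pattern2", "full")) {
    A31 <- keep("A31", concludeFromEvidence(ds, p3, CB, c3, slug = "A31"))
    A32 <- keep("A32", concludeFromEvidence(ds, p5, CB, c4, slug = "A32"))
    keep(if (both) "A30.evidence" else "A30",
         concludeFromEvidence(ds, p1, CB, c(A31, A32, A4),
                              slug = if (both) "A30-evidence" else "A30"))
  }

  ## -- alternative interpretation: the data read as GGT evidence --------
  if (variant %in% c("alternative", "full")) {
    A45 <- keep("A45", makeAssertion(ds,
      keep("p45", formalizeProperty(ds, assay1, cls("achieves_objective"),
                                    cls("ggt_activity_measurement"))),
      CB, role = "interpretation", slug = "A45"))
    A46 <- keep("A46", makeAssertion(ds,
      keep("p46", formalizeProperty(ds, cls("ggt_activity_measurement"),
                                    cls("determines"), cls("ggt_activity"))),
      CB, role = "terminological", slug = "A46"))
    A43 <- keep("A43", concludeFromEvidence(ds,
      keep("p43", formalizeProperty(ds, dataItem1, cls("is_measurement_of"),
                                    cls("ggt_activity"))),
      CB, c(A9, A10, A45, A46), slug = "A43"))
    A42 <- keep("A42", concludeFromEvidence(ds,
      keep("p42", formalizeProperty(ds, sample1, cls("has_quality"),
                                    cls("ggt_activity"))),
      CB, c(A6, A7, A43), slug = "A42"))
    A44 <- keep("A44", makeAssertion(ds,
      keep("p44", formalizeProperty(ds, cls("ggt_activity"), cls("is_borne_by"),
                                    cls("ggt_enzyme"))),
      CB, role = "terminological", slug = "A44"))
    A41 <- keep("A41", concludeFromEvidence(ds, p5, CB, c4, slug = "A41"))
    keep("A40", concludeFromEvidence(ds,
      keep("p40", formalizeSomeSome(ds, cls("ggt_enzyme"), cls("is_isolated_from"),
                                    cls("rat_liver"), slug = "proposition-40")),
      CB, c(A42, A44, A41), slug = "A40"))
  }

  list(dataset = ds, ids = ids)
}
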