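rdfType <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

test_that("formalizeType and formalizeProperty mint fresh one-triple graphs", {
  ds <- newDataset()
  assay <- addClassTerm(ds, "gamma_ghs_assay", "γ-GHS assay")
  a1 <- addIndividual(ds, "assay-1", "assay-1")
  p <- formalizeType(ds, a1, assay)
  tr <- namedGraph(ds, p)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$s, a1)
  expect_equal(tr$p, rdfType)
  expect_equal(tr$o, assay)
  p2 <- formalizeType(ds, a1, "http://www.w3.org/2002/07/owl#Thing")
  expect_false(identical(p, p2))  # fresh IRIs each call
  expect_equal(nrow(namedGraph(ds, p2)), 1L)

  p3 <- formalizeProperty(ds, "http://e.org/sample-1", "http://e.org/is_input_to",
                          a1)
  expect_equal(namedGraph(ds, p3)$p, "http://e.org/is_input_to")
  p4 <- formalizeProperty(ds, "http://e.org/x", "http://e.org/p",
                          rdfLiteral("42", datatype = "http://www.w3.org/2001/XMLSchema#integer"))
  tr4 <- namedGraph(ds, p4)
  expect_equal(tr4$o_kind, "literal")
  expect_equal(tr4$o, "42")
})

test_that("formalizeSomeSome expands to the hand-built OWL 2 RDF mapping", {
  ds <- newDataset()
  A <- addClassTerm(ds, "gs_enzyme", "GS-enzyme")
  r <- addPropertyTerm(ds, "is_isolated_from", "isolated from")
  B <- addClassTerm(ds, "rat_liver", "rat liver")
  p <- formalizeSomeSome(ds, A, r, B)
  tr <- namedGraph(ds, p)
  ## manual expansion of (A and r some B): instance typing, class node,
  ## intersection with a 2-element list, restriction with
  ## onProperty/someValuesFrom
  owl <- "http://www.w3.org/2002/07/owl#"
  rdf <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
  expect_equal(nrow(tr), 10L)
  expect_equal(sum(tr$p == rdfType), 3L)
  expect_equal(sum(tr$p == paste0(owl, "intersectionOf")), 1L)
  expect_equal(sum(tr$p == paste0(rdf, "first")), 2L)
  expect_equal(sum(tr$p == paste0(rdf, "rest")), 2L)
  expect_equal(tr$o[tr$p == paste0(owl, "onProperty")], r)
  expect_equal(tr$o[tr$p == paste0(owl, "someValuesFrom")], B)
  expect_equal(tr$o[tr$p == paste0(rdf, "first") & tr$o_kind == "iri"], A)
  expect_true(paste0(rdf, "nil") %in% tr$o[tr$p == paste0(rdf, "rest")])
  expect_equal(propositionLabel(ds, p),
               "some GS-enzyme isolated from some rat liver")
  ## reflexive use of the same class on both sides is well-formed
  p2 <- formalizeSomeSome(ds, A, r, A)
  expect_equal(nrow(namedGraph(ds, p2)), 10L)
})

test_that("makeAssertion wires subject, agents, provenance and role", {
  ds <- newDataset()
  ag <- addAgent(ds, "A. Meister", "AM")
  rp <- addReport(ds, "Meister 1985")
  part <- addReportPart(ds, rp, "paragraph 2", text = "GS was isolated from rat liver.")
  A <- addClassTerm(ds, "gs_enzyme", "GS-enzyme")
  r <- addPropertyTerm(ds, "is_isolated_from", "isolated from")
  B <- addClassTerm(ds, "rat_liver", "rat liver")
  p1 <- formalizeSomeSome(ds, A, r, B)
  a1 <- makeAssertion(ds, p1, ag, part, role = "conclusion")
  voc <- vocabulary(ds)
  q <- quads(ds)
  expect_true(any(q$s == a1 & q$p == voc[["asserts"]] & q$o == p1))
  expect_true(any(q$s == a1 & q$p == voc[["is_assertion_made_by"]] & q$o == ag))
  expect_true(any(q$s == a1 & q$p == voc[["is_assertion_made_in"]] & q$o == part))
  expect_equal(assertionLabel(ds, a1),
               "! some GS-enzyme isolated from some rat liver ! AM")
  ## curator claim without report link
  a2 <- makeAssertion(ds, p1, ag)
  expect_false(any(quads(ds)$s == a2 &
                     quads(ds)$p == voc[["is_assertion_made_in"]]))
  expect_error(makeAssertion(ds, character(0), ag), class = "semevid_NO_SUBJECT")
  expect_error(makeAssertion(ds, p1, character(0)), class = "semevid_NO_AGENT")
  expect_error(makeAssertion(ds, p1, ag, role = "bogus"),
               class = "semevid_BAD_ROLE")
  expect_error(addAgent(ds, "x", "lower"), class = "semevid_BAD_INITIALS")
})

test_that("reiterate shares the source proposition and links inference", {
  fx <- gsFx("base")
  ds <- fx$dataset
  expect_equal(semevid:::assertedPropositions(ds, fx$ids[["A1"]]),
               semevid:::assertedPropositions(ds, fx$ids[["A2"]]))
  expect_equal(directPremises(ds, fx$ids[["A1"]]), unname(fx$ids[["A2"]]))

  ## reiterating a reiteration chains two inference links
  fx2 <- buildGsCaseStudy("base")
  ag <- addAgent(fx2$dataset, "Z. Zed", "ZZ")
  a3 <- reiterate(fx2$dataset, fx2$ids[["A1"]], ag)
  expect_equal(directPremises(fx2$dataset, a3), unname(fx2$ids[["A1"]]))
  expect_true(fx2$ids[["A2"]] %in% premisesClosure(fx2$dataset, a3))
  ## shared-subject dependency is detectable
  rep <- q3Independence(fx2$dataset, fx2$ids[["p1"]])
  expect_true(any(rep@dependentPairs[, 1] == a3 &
                    rep@dependentPairs[, 2] == fx2$ids[["A1"]]))
  expect_error(reiterate(fx2$dataset, "http://nowhere/a", ag),
               class = "semevid_UNKNOWN_ASSERTION")
})

test_that("composition concatenates subjects and guards its inputs", {
  fx <- buildGsCaseStudy("base")
  ds <- fx$dataset
  comp <- fx$ids[["c1"]]
  props <- semevid:::assertedPropositions(ds, comp)
  expect_equal(props, unname(fx$ids[c("p3", "p4", "p5")]))
  agents <- semevid:::assertingAgents(ds, comp)
  expect_setequal(agents, unname(fx$ids[c("ST", "JL", "AM")]))
  lab <- assertionLabel(ds, comp)
  expect_match(lab, " AND ", fixed = TRUE)
  expect_error(composeAssertions(ds, fx$ids[["A3"]]),
               class = "semevid_TOO_FEW_PARTS")
  expect_error(composeAssertions(ds, c(fx$ids[["A3"]], fx$ids[["A3"]])),
               class = "semevid_DUPLICATE_PART")
})

test_that("linkInference is idempotent and rejects self-links", {
  fx <- buildGsCaseStudy("base")
  ds <- fx$dataset
  n0 <- nrow(quads(ds))
  linkInference(ds, fx$ids[["A1"]], fx$ids[["A2"]])  # already present
  expect_equal(nrow(quads(ds)), n0)
  expect_error(linkInference(ds, fx$ids[["A1"]], fx$ids[["A1"]]),
               class = "semevid_SELF_INFERENCE")
})

test_that("attribution propositions support stacked interpretation layers", {
  fx <- buildGsCaseStudy("base")
  ds <- fx$dataset
  cb <- fx$ids[["CB"]]
  ## the fixture's meta layer: CB asserts that A10 was made in the 1972
  ## report
  trM <- namedGraph(ds, fx$ids[["pM"]])
  expect_equal(trM$s, unname(fx$ids[["A10"]]))
  expect_equal(trM$o, unname(fx$ids[["tate1972"]]))
  ## meta-asserting the meta-assertion: a second nesting layer
  p2 <- formalizeAttribution(ds, fx$ids[["M1"]], fx$ids[["meister1985"]])
  m2 <- makeAssertion(ds, p2, cb)
  expect_true(m2 %in% assertionsOnSubject(ds, p2))
  diag <- validateDataset(ds)
  expect_equal(nrow(diag[diag$severity == "error", ]), 0L)
})

test_that("the two curator-conclusion patterns differ in their closure", {
  p1fx <- gsFx("pattern1")
  expect_true(p1fx$ids[["A2"]] %in%
                premisesClosure(p1fx$dataset, p1fx$ids[["A30"]]))
  p2fx <- gsFx("pattern2")
  cl <- premisesClosure(p2fx$dataset, p2fx$ids[["A30"]])
  expect_false(p2fx$ids[["A2"]] %in% cl)
  expect_true(all(p2fx$ids[c("A9", "A10", "A11", "A12")] %in% cl))
  ## single premise, single proposition: one assertion plus a direct edge
  fx <- buildGsCaseStudy("base")
  ds <- fx$dataset
  a <- concludeFromEvidence(ds, fx$ids[["p3"]], fx$ids[["CB"]],
                            fx$ids[["c3"]])
  expect_equal(directPremises(ds, a), unname(fx$ids[["c3"]]))
  expect_equal(semevid:::roleOf(ds, a), "interpretation")
  expect_error(concludeFromEvidence(ds, fx$ids[["p3"]], fx$ids[["CB"]],
                                    character(0)),
               class = "semevid_NO_PREMISE")
})

test_that("builders always mint fresh IRIs", {
  ds <- newDataset()
  ag <- addAgent(ds, "X", "XX")
  seen <- character(0)
  for (k in 1:10) {
    p <- formalizeType(ds, paste0("http://e.org/i", k), "http://e.org/C")
    a <- makeAssertion(ds, p, ag)
    expect_false(p %in% seen)
    expect_false(a %in% seen)
    seen <- c(seen, p, a)
  }
  expect_error(mintIri(ds, "agent", slug = "agent-1"),
               class = "semevid_IRI_EXISTS")
})
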