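test_that("direct premises follow the recorded links", {
  fx <- gsFx("base")
  ds <- fx$dataset
  expect_equal(directPremises(ds, fx$ids[["A1"]]), unname(fx$ids[["A2"]]))
  expect_length(directPremises(ds, fx$ids[["A9"]]), 0L)  # factual, not justified
  expect_error(directPremises(ds, "http://nowhere/x"),
               class = "semevid_UNKNOWN_ASSERTION")
})

test_that("the fixture closure reaches the whole argumentative trail", {
  fx <- gsFx("base")
  ds <- fx$dataset
  cl <- premisesClosure(ds, fx$ids[["A1"]])
  expect_true(all(fx$ids[c("A2", "A3", "A4", "A5", "A6", "A7", "A8",
                           "A9", "A10", "A11", "A12",
                           "A15", "A16", "A17", "A18", "A19", "A20",
                           "c1", "c2", "c3", "c4")] %in% cl))
  expect_length(premisesClosure(ds, fx$ids[["A9"]]), 0L)
  bo <- basedOn(ds, fx$ids[["A1"]])
  expect_setequal(bo$reports, unname(fx$ids[c("meister1985", "tate1972")]))
  expect_length(bo$texts, 2L)
})

test_that("closure equals brute-force reachability on seeded networks", {
  for (s in 1:30) {
    d <- genSynthetic(syntheticParams(seed = s, n_conclusions = 2,
                                      max_depth = 2, branching = c(1, 2),
                                      p_composite = 0.5, p_reiterate = 0.3))
    q <- quads(d)
    voc <- vocabulary(d)
    as <- unique(q$s[is.na(q$graph) &
                       q$p == "http://www.w3.org/1999/02/22-rdf-syntax-ns#type" &
                       q$o == voc[["assertion"]]])
    for (a in as)
      expect_equal(premisesClosure(d, a), oracleClosure(d, a),
                   info = paste("seed", s, a))
  }
})

test_that("conclusions closure is the exact inverse of premises closure", {
  fx <- gsFx("base")
  expect_true(fx$ids[["A1"]] %in%
                conclusionsClosure(fx$dataset, fx$ids[["A2"]]))
  expect_length(conclusionsClosure(fx$dataset, fx$ids[["A1"]]), 0L)
  for (s in c(3, 17)) {
    d <- genSynthetic(syntheticParams(seed = s, n_conclusions = 2,
                                      max_depth = 2, branching = c(1, 2)))
    q <- quads(d)
    voc <- vocabulary(d)
    as <- unique(q$s[is.na(q$graph) &
                       q$p == "http://www.w3.org/1999/02/22-rdf-syntax-ns#type" &
                       q$o == voc[["assertion"]]])
    for (x in as) for (y in premisesClosure(d, x))
      expect_true(x %in% conclusionsClosure(d, y))
    for (x in as) for (y in conclusionsClosure(d, x))
      expect_true(x %in% premisesClosure(d, y))
  }
})

test_that("closure grows monotonically when edges are added", {
  fx <- buildGsCaseStudy("base")
  ds <- fx$dataset
  before <- premisesClosure(ds, fx$ids[["A1"]])
  boBefore <- basedOn(ds, fx$ids[["A1"]])
  ## a new premise made in a new report grows reports by exactly that one
  rep <- addReport(ds, "Extra 2001", slug = "extra-2001")
  part <- addReportPart(ds, rep, "page 1")
  ag <- addAgent(ds, "N. New", "NN")
  p <- formalizeType(ds, paste0(prefixes(ds)[["ex"]], "extra-ind"),
                     "http://e.org/C")
  a <- makeAssertion(ds, p, ag, part)
  linkInference(ds, fx$ids[["A9"]], a)
  after <- premisesClosure(ds, fx$ids[["A1"]])
  expect_true(all(before %in% after))
  expect_true(a %in% after)
  boAfter <- basedOn(ds, fx$ids[["A1"]])
  expect_setequal(setdiff(boAfter$reports, boBefore$reports), rep)
})

test_that("index lookups resolve reports, agents and subjects", {
  fx <- gsFx("base")
  ds <- fx$dataset
  inTate <- assertionsInReport(ds, fx$ids[["tate1972"]])
  expect_true(all(fx$ids[c("A2", "A3", "A9", "A10")] %in% inTate))
  expect_false(fx$ids[["A1"]] %in% inTate)
  expect_true(fx$ids[["A1"]] %in% assertionsByAgent(ds, fx$ids[["AM"]]))
  expect_false(fx$ids[["A1"]] %in% assertionsByAgent(ds, fx$ids[["JL"]]))
  onP1 <- assertionsOnSubject(ds, fx$ids[["p1"]])
  expect_setequal(onP1, unname(fx$ids[c("A1", "A2")]))
  expect_setequal(agentsAsserting(ds, fx$ids[["p1"]]),
                  unname(fx$ids[c("AM", "ST", "JL")]))
  p1fx <- gsFx("pattern1")
  expect_true(all(p1fx$ids[c("A1", "A2", "A30")] %in%
                    assertionsOnSubject(p1fx$dataset, p1fx$ids[["p1"]])))
  expect_true(p1fx$ids[["CB"]] %in%
                agentsAsserting(p1fx$dataset, p1fx$ids[["p1"]]))
  expect_error(assertionsOnSubject(newDataset(), "http://nowhere/p"),
               class = "semevid_UNKNOWN_RESOURCE")
})

test_that("cycle detection finds cycles and clears DAGs", {
  expect_length(detectCycles(gsFx("full")$dataset), 0L)
  ds <- newDataset()
  ag <- addAgent(ds, "X", "XX")
  a <- makeAssertion(ds, formalizeType(ds, "http://e.org/i1", "http://e.org/C"), ag)
  b <- makeAssertion(ds, formalizeType(ds, "http://e.org/i2", "http://e.org/C"), ag)
  linkInference(ds, a, b)
  linkInference(ds, b, a)
  cyc <- detectCycles(ds)
  expect_length(cyc, 1L)
  expect_setequal(cyc[[1]], c(a, b))
  for (s in 1:15) {
    d <- genSynthetic(syntheticParams(seed = s, n_conclusions = 1,
                                      max_depth = 2, branching = c(1, 2)))
    expect_length(detectCycles(d), 0L)
  }
})

test_that("materialization writes the inferred relations to a named graph", {
  fx <- buildGsCaseStudy("base")
  ds <- fx$dataset
  materializeInferred(ds)
  tr <- namedGraph(ds, "urn:see:inferred")
  voc <- vocabulary(ds)
  cl <- premisesClosure(ds, fx$ids[["A1"]])
  inferred <- tr$o[tr$s == fx$ids[["A1"]] & tr$p == voc[["is_inferred_from"]]]
  expect_setequal(inferred, cl)
  basedRep <- tr$o[tr$s == fx$ids[["A1"]] & tr$p == voc[["is_based_on_report"]]]
  expect_setequal(basedRep, unname(fx$ids[c("meister1985", "tate1972")]))
})
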