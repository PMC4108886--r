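exIri <- function(ds, x) paste0(prefixes(ds)[["ex"]], x)

test_that("Q1/Q2 find the asserted location and its reports", {
  fx <- gsFx("full")
  ds <- fx$dataset
  defs <- gsQueryDefaults(ds)
  expect_equal(q1Locations(ds, defs$entityClass, defs$relation),
               exIri(ds, "rat_liver"))
  expect_length(q1Locations(newDataset(), defs$entityClass, defs$relation), 0L)
  expect_setequal(q2Reports(ds, defs$entityClass, defs$relation),
                  unname(fx$ids[c("meister1985", "tate1972")]))
  ## a synthetic record with two locations returns both fillers
  ds2 <- newDataset()
  ag <- addAgent(ds2, "X", "XX")
  E <- addClassTerm(ds2, "enzyme", "enzyme")
  r <- addPropertyTerm(ds2, "located_in", "located in")
  liver <- addClassTerm(ds2, "liver", "liver")
  kidney <- addClassTerm(ds2, "kidney", "kidney")
  makeAssertion(ds2, formalizeSomeSome(ds2, E, r, liver), ag)
  makeAssertion(ds2, formalizeSomeSome(ds2, E, r, kidney), ag)
  expect_setequal(q1Locations(ds2, E, r), c(liver, kidney))
  ## an assertion without report link contributes nothing to Q2
  expect_length(q2Reports(ds2, E, r), 0L)
})

test_that("Q3 detects dependency and shared authorship", {
  fx <- gsFx("full")
  ds <- fx$dataset
  rep <- q3Independence(ds, fx$ids[["p1"]])
  expect_false(rep@independent)
  expect_true(any(rep@dependentPairs[, 1] == fx$ids[["A1"]] &
                    rep@dependentPairs[, 2] == fx$ids[["A2"]]))
  key <- paste(sort(unname(fx$ids[c("A1", "A2")])), collapse = "|")
  expect_true(fx$ids[["AM"]] %in% rep@sharedAgents[[key]])
  ## proposition asserted only once (the meta proposition): vacuously
  ## independent
  rep1 <- q3Independence(ds, fx$ids[["pM"]])
  expect_true(rep1@independent)
  ## two unlinked assertions by disjoint agents are independent
  ds2 <- newDataset()
  a1 <- addAgent(ds2, "X", "XX"); a2 <- addAgent(ds2, "Y", "YY")
  p <- formalizeType(ds2, "http://e.org/i", "http://e.org/C")
  makeAssertion(ds2, p, a1)
  makeAssertion(ds2, p, a2)
  expect_true(q3Independence(ds2, p)@independent)
})

test_that("Q4/Q5 locate the experimental evidence and its techniques", {
  fx <- gsFx("full")
  ds <- fx$dataset
  expect_equal(q4ExperimentalEvidence(ds, fx$ids[["A1"]]),
               unname(fx$ids[["tate1972"]]))
  ## narrowing the class set to purification only still answers Tate 1972
  expect_equal(q4ExperimentalEvidence(ds, fx$ids[["A1"]],
                                      exIri(ds, "tlm_purification")),
               unname(fx$ids[["tate1972"]]))
  ## a closure without experimental subjects yields nothing
  expect_length(q4ExperimentalEvidence(ds, fx$ids[["A9"]]), 0L)

  q5 <- q5Techniques(ds, fx$ids[["A1"]])
  pairs <- unique(q5[, c("observation", "technique")])
  expect_equal(nrow(pairs), 2L)
  expect_setequal(paste(pairs$observation, pairs$technique),
                  c(paste(fx$ids[["p3"]], exIri(ds, "gamma_ghs_assay")),
                    paste(fx$ids[["p5"]], exIri(ds, "tlm_purification"))))
  ## the printed reading: sample extracted from rat liver via TLM
  ## purification; the sample has GS-activity via the γ-GHS assay
  expect_equal(propositionLabel(ds, fx$ids[["p5"]]),
               "sample-1 isolated from rat liver")
  expect_equal(propositionLabel(ds, fx$ids[["p3"]]),
               "sample-1 has GS-activity")
  expect_equal(nrow(q5Techniques(ds, fx$ids[["A9"]])), 0L)
})

test_that("Q6 names the creator of the account", {
  fx <- gsFx("full")
  ds <- fx$dataset
  expect_equal(q6AccountCreator(ds, unname(fx$ids[c("A9", "A10", "A11", "A12")])),
               unname(fx$ids[["CB"]]))
  expect_equal(semevid:::resourceLabel(ds, q6AccountCreator(
    ds, unname(fx$ids[["A10"]]))), "C. Bölling")
  expect_length(q6AccountCreator(gsFx("base")$dataset, "http://nowhere/a"), 0L)
  ## two curators annotating disjoint assertions are both returned
  fx2 <- buildGsCaseStudy("base")
  ds2 <- fx2$dataset
  zz <- addAgent(ds2, "Z. Zed", "ZZ")
  makeAssertion(ds2, formalizeAttribution(ds2, fx2$ids[["A9"]],
                                          fx2$ids[["tate1972"]]), zz)
  expect_setequal(q6AccountCreator(ds2, unname(fx2$ids[c("A9", "A10")])),
                  c(unname(fx2$ids[["CB"]]), zz))
})

test_that("emitted SPARQL reproduces the programmatic answers", {
  fx <- gsFx("full")
  ds <- fx$dataset
  defs <- gsQueryDefaults(ds)
  expcl <- gsExperimentalClasses(ds)

  m <- runSparql(ds, emitSparql(ds, "Q1", entityClass = defs$entityClass,
                                relation = defs$relation))
  expect_equal(sparqlCol(m), q1Locations(ds, defs$entityClass, defs$relation))

  m <- runSparql(ds, emitSparql(ds, "Q2", entityClass = defs$entityClass,
                                relation = defs$relation))
  expect_equal(sparqlCol(m), q2Reports(ds, defs$entityClass, defs$relation))

  m <- runSparql(ds, emitSparql(ds, "Q3", proposition = fx$ids[["p1"]]))
  rep <- q3Independence(ds, fx$ids[["p1"]])
  expect_setequal(paste(m[, 1], m[, 2]),
                  paste(rep@dependentPairs[, 1], rep@dependentPairs[, 2]))

  m <- runSparql(ds, emitSparql(ds, "Q4", assertion = fx$ids[["A1"]],
                                experimentalClasses = expcl))
  expect_equal(sparqlCol(m), q4ExperimentalEvidence(ds, fx$ids[["A1"]]))

  m <- runSparql(ds, emitSparql(ds, "Q5", assertion = fx$ids[["A1"]],
                                experimentalClasses = expcl))
  q5 <- unique(q5Techniques(ds, fx$ids[["A1"]])[, c("observation", "technique")])
  expect_setequal(paste(m[, 1], m[, 2]), paste(q5$observation, q5$technique))

  m <- runSparql(ds, emitSparql(ds, "Q6",
                                assertions = unname(fx$ids[c("A9", "A10")])))
  expect_equal(sparqlCol(m), q6AccountCreator(ds, unname(fx$ids[c("A9", "A10")])))

  expect_error(emitSparql(ds, "Q7"), class = "semevid_UNKNOWN_QUERY")
})

test_that("programmatic and SPARQL routes agree on synthetic datasets", {
  for (s in c(2, 5, 9)) {
    d <- genSynthetic(syntheticParams(seed = s, n_conclusions = 2,
                                      max_depth = 2, branching = c(1, 2),
                                      p_composite = 0.6))
    ex <- prefixes(d)[["ex"]]
    ## test the (class, relation) pairs that occur in existential
    ## subjects, plus one absent pair as a negative control
    pats <- unique(do.call(rbind, lapply(namedGraphs(d), function(g) {
      ss <- semevid:::matchSomeSome(namedGraph(d, g))
      if (is.null(ss)) NULL
      else data.frame(cl = ss$classA, r = ss$property, stringsAsFactors = FALSE)
    })))
    pats <- rbind(pats, data.frame(cl = paste0(ex, "class-1"),
                                   r = paste0(ex, "no-such-prop"),
                                   stringsAsFactors = FALSE))
    for (i in seq_len(min(nrow(pats), 4))) {
      prog <- q1Locations(d, pats$cl[i], pats$r[i])
      m <- runSparql(d, emitSparql(d, "Q1", entityClass = pats$cl[i],
                                   relation = pats$r[i]))
      expect_equal(sparqlCol(m), prog,
                   info = sprintf("seed %d %s %s", s, pats$cl[i], pats$r[i]))
    }
    ## Q3 over every multiply-asserted proposition
    q <- quads(d)
    voc <- vocabulary(d)
    am <- q[is.na(q$graph) & q$p == voc[["asserts"]], c("s", "o")]
    multi <- names(which(table(am$o) > 1))
    for (p in utils::head(multi, 4)) {
      rep <- q3Independence(d, p)
      m <- runSparql(d, emitSparql(d, "Q3", proposition = p))
      got <- if (nrow(m) && ncol(m) == 2) paste(m[, 1], m[, 2]) else character(0)
      expect_true(setequal(got, paste(rep@dependentPairs[, 1],
                                      rep@dependentPairs[, 2])),
                  info = paste("seed", s, p))
    }
  }
})
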