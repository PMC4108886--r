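test_that("new datasets are empty, carry prefixes and are deterministic", {
  ds <- newDataset()
  expect_s4_class(ds, "EvidenceDataset")
  expect_equal(nrow(quads(ds)), 0L)
  expect_length(namedGraphs(ds), 0L)
  txt <- serializeDataset(ds, "trig")
  for (pfx in names(defaultPrefixes()))
    expect_match(txt, sprintf("@prefix %s:", pfx), all = FALSE)
  expect_true(isomorphicDatasets(newDataset(), newDataset()))
  expect_identical(serializeDataset(newDataset()), serializeDataset(newDataset()))
  expect_error(newDataset(c(bad = "not an iri")), class = "semevid_BAD_PREFIX")
})

test_that("named graphs are added, retrieved and guarded", {
  ds <- newDataset()
  g1 <- paste0(prefixes(ds)[["ex"]], "proposition-10")
  tr <- triple(paste0(prefixes(ds)[["ex"]], "assay-1"),
               paste0("http://www.w3.org/1999/02/22-rdf-syntax-ns#", "type"),
               paste0(prefixes(ds)[["ex"]], "gamma_ghs_assay"))
  addNamedGraph(ds, g1, tr)
  expect_equal(nrow(namedGraph(ds, g1)), 1L)
  expect_equal(namedGraph(ds, g1)$o, tr$o)
  expect_error(addNamedGraph(ds, g1, tr), class = "semevid_DUPLICATE_GRAPH")
  expect_error(addNamedGraph(ds, paste0(g1, "b"), tr[0, ]),
               class = "semevid_EMPTY_SUBJECT")
  addNamedGraph(ds, paste0(g1, "b"), tr)
  expect_length(namedGraphs(ds), 2L)
  expect_error(namedGraph(ds, "http://nowhere/"), class = "semevid_UNKNOWN_GRAPH")
})

test_that("TriG and N-Quads round-trip all fixture variants isomorphically", {
  for (variant in c("base", "pattern1", "pattern2", "alternative", "full")) {
    ds <- gsFx(variant)$dataset
    for (fmt in c("trig", "nquads")) {
      txt <- serializeDataset(ds, fmt)
      back <- parseDataset(txt, fmt)
      expect_true(isomorphicDatasets(ds, back),
                  info = sprintf("%s / %s", variant, fmt))
    }
  }
  empty <- parseDataset(serializeDataset(newDataset(), "trig"), "trig")
  expect_equal(nrow(quads(empty)), 0L)
})

test_that("serialization is deterministic and stable under re-parse", {
  ds <- gsFx("full")$dataset
  txt <- serializeDataset(ds, "trig")
  expect_identical(serializeDataset(ds, "trig"), txt)
  expect_identical(serializeDataset(parseDataset(txt, "trig"), "trig"), txt)
  nq <- serializeDataset(ds, "nquads")
  expect_identical(serializeDataset(parseDataset(nq, "nquads"), "nquads"), nq)
})

test_that("seeded synthetic datasets round-trip isomorphically", {
  for (s in 1:25) {
    d <- genSynthetic(syntheticParams(seed = s, n_conclusions = 2,
                                      max_depth = 2, branching = c(1, 2)))
    expect_true(isomorphicDatasets(d, parseDataset(serializeDataset(d, "trig"),
                                                   "trig")),
                info = paste("seed", s))
  }
})

test_that("parser handles the TriG surface syntax and reports positions", {
  txt <- paste(
    "@prefix ex: <http://e.org/> .",
    "PREFIX foo: <http://f.org/>",
    "ex:s ex:p ex:o ; ex:q \"lit\"@en , \"42\"^^ex:int .",
    "ex:s2 a foo:T .",
    "GRAPH ex:g { _:b ex:p 3 . _:b ex:q true . }",
    sep = "\n")
  ds <- parseDataset(txt, "trig")
  q <- quads(ds)
  expect_equal(sum(is.na(q$graph)), 4L)
  expect_equal(sum(!is.na(q$graph)), 2L)
  expect_true("http://f.org/T" %in% q$o)
  expect_equal(q$o_lang[q$o == "lit"], "en")
  expect_equal(q$o_dt[q$o == "3"],
               "http://www.w3.org/2001/XMLSchema#integer")
  err <- tryCatch(parseDataset("ex:s ex:p ex:o .", "trig"), error = identity)
  expect_s3_class(err, "semevid_PARSE_ERROR")
  expect_match(conditionMessage(err), "line 1")
  err2 <- tryCatch(parseDataset("@prefix ex: <http://e.org/> .\nex:s ex:p @ .",
                                "trig"), error = identity)
  expect_match(conditionMessage(err2), "line 2, column")
  expect_error(serializeDataset(newDataset(), "turtle"))
})

test_that("literal escapes survive a round trip", {
  ds <- newDataset()
  s <- "http://e.org/s"
  addTriples(ds, triple(s, "http://e.org/p",
                        rdfLiteral("a \"quoted\"\nline\twith \\ back γ")))
  back <- parseDataset(serializeDataset(ds, "trig"), "trig")
  expect_true(isomorphicDatasets(ds, back))
  expect_true(isomorphicDatasets(ds, parseDataset(serializeDataset(ds, "nquads"),
                                                  "nquads")))
})

test_that("dataset isomorphism agrees with exhaustive bijection search", {
  ds <- gsFx("base")$dataset
  expect_true(isomorphicDatasets(ds, ds))
  ds2 <- parseDataset(serializeDataset(ds, "trig"), "trig")
  addTriples(ds2, triple("http://e.org/extra", "http://e.org/p", "http://e.org/o"))
  expect_false(isomorphicDatasets(ds, ds2))

  ## bnode-renamed copies of the existential-pattern graphs
  mk <- function(rename) {
    d <- newDataset()
    p <- formalizeSomeSome(d, "http://e.org/A", "http://e.org/r", "http://e.org/B")
    if (rename) {
      q <- quads(d)
      q$s <- sub("^_:n", "_:zz", q$s)
      q$o[q$o_kind == "bnode"] <- sub("^_:n", "_:zz", q$o[q$o_kind == "bnode"])
      d@env$quads <- q
      d@env$qkeys <- NULL
    }
    d
  }
  d1 <- mk(FALSE); d2 <- mk(TRUE)
  expect_true(isomorphicDatasets(d1, d2))
  g <- namedGraphs(d1)[1]
  t1 <- namedGraph(d1, g); t2 <- namedGraph(d2, g)
  expect_true(bruteGraphIso(t1, t2))
  ## flip one ground term: both routes must reject
  t3 <- t2
  t3$o[t3$o == "http://e.org/B"] <- "http://e.org/C"
  expect_false(bruteGraphIso(t1, t3))
  d2@env$quads$o[d2@env$quads$o == "http://e.org/B"] <- "http://e.org/C"
  d2@env$qkeys <- NULL
  expect_false(isomorphicDatasets(d1, d2))
})

test_that("my TriG output is valid for an independent RDF parser", {
  ds <- gsFx("base")$dataset
  trig <- tempfile(fileext = ".trig")
  on.exit(unlink(trig))
  writeDataset(ds, trig, "trig")
  py <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from rdflib import Dataset",
    "ds = Dataset()",
    "ds.parse(sys.argv[1], format='trig')",
    "print(sum(1 for _ in ds.quads((None, None, None, None))))"), py)
  out <- system2("python", c(py, trig), stdout = TRUE, stderr = TRUE)
  expect_equal(as.integer(out[length(out)]), nrow(quads(ds)))
})
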