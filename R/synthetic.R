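## Seeded generator of synthetic evidence networks: acyclic argument
## DAGs with randomly shaped proposition subjects, used by the property
## tests (closure vs. brute force, round-trip isomorphism, validation
## monotonicity). Networks are acyclic by construction (premises are
## always freshly minted assertions).

#' Parameters of the synthetic evidence-network generator
#'
#' @param seed integer RNG seed; the generated dataset is a deterministic
#'   function of the parameters.
#' @param n_conclusions number of top-level conclusion assertions.
#' @param max_depth depth of the justification trails below each
#'   conclusion.
#' @param branching length-2 integer range of premises per justified
#'   assertion.
#' @param p_composite probability that multiple premises are bundled
#'   into a composite assertion.
#' @param p_reiterate probability that a premise shares its conclusion's
#'   proposition (a reiteration) instead of minting a new subject.
#' @param n_agents,n_reports numbers of agents and reports (one part
#'   each) to draw provenance from.
#' @return validated parameter list of class \code{syntheticParams}.
#' @export
syntheticParams <- function(seed = 1L, n_conclusions = 3L, max_depth = 3L,
                            branching = c(1L, 3L), p_composite = 0.4,
                            p_reiterate = 0.2, n_agents = 4L, n_reports = 3L) {
  p <- list(seed = as.integer(seed), n_conclusions = as.integer(n_conclusions),
            max_depth = as.integer(max_depth), branching = as.integer(branching),
            p_composite = p_composite, p_reiterate = p_reiterate,
            n_agents = as.integer(n_agents), n_reports = as.integer(n_reports))
  ok <- length(p$branching) == 2L && !anyNA(unlist(p))
  seeAssert(ok, "INVALID_PARAMS", "branching must be a length-2 integer range")
  seeAssert(p$n_conclusions > 0L && p$max_depth >= 0L && p$n_agents > 0L &&
              p$n_reports > 0L, "INVALID_PARAMS", "counts must be positive")
  seeAssert(p$branching[1] >= 1L && p$branching[2] >= p$branching[1],
            "INVALID_PARAMS", "branching range must be non-empty and >= 1")
  seeAssert(p$p_composite >= 0 && p$p_composite <= 1 &&
              p$p_reiterate >= 0 && p$p_reiterate <= 1,
            "INVALID_PARAMS", "probabilities must be in [0, 1]")
  seeAssert(p$n_agents <= 676L, "INVALID_PARAMS",
            "at most 676 agents (two-letter initials)")
  structure(p, class = "syntheticParams")
}

#' Generate a synthetic evidence network
#'
#' @param params a \code{\link{syntheticParams}} object.
#' @return an \code{\linkS4class{EvidenceDataset}} satisfying the model
#'   invariants (validates with zero errors, acyclic inference
#'   structure).
#' @examples
#' ds <- genSynthetic(syntheticParams(seed = 7))
#' length(detectCycles(ds))  # 0
#' @export
genSynthetic <- function(params = syntheticParams()) {
  if (!inherits(params, "syntheticParams")) params <- do.call(syntheticParams, params)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(params$seed)

  ds <- newDataset()
  agents <- vapply(seq_len(params$n_agents), function(i) {
    ini <- paste0(LETTERS[(i - 1L) %/% 26L + 1L], LETTERS[(i - 1L) %% 26L + 1L])
    addAgent(ds, sprintf("Agent %d", i), ini, slug = sprintf("agent-%d", i))
  }, "")
  parts <- vapply(seq_len(params$n_reports), function(i) {
    r <- addReport(ds, sprintf("Report %d (20%02d)", i, i),
                   slug = sprintf("report-%d", i))
    addReportPart(ds, r, "paragraph 1",
                  text = sprintf("Synthetic statement %d.", i),
                  slug = sprintf("report-%d-part", i))
  }, "")
  classes <- vapply(1:6, function(i)
    addClassTerm(ds, sprintf("class-%d", i), sprintf("class %d", i)), "")
  props <- vapply(1:4, function(i)
    addPropertyTerm(ds, sprintf("prop-%d", i), sprintf("relates %d", i)), "")

  newIndividual <- local({
    n <- 0L
    function() {
      n <<- n + 1L
      addIndividual(ds, sprintf("individual-%d", n), sprintf("individual %d", n))
    }
  })
  randProposition <- function() {
    switch(sample(c("type", "property", "somesome"), 1L),
      type = formalizeType(ds, newIndividual(), sample(classes, 1L)),
      property = formalizeProperty(ds, newIndividual(), sample(props, 1L),
                                   newIndividual()),
      somesome = formalizeSomeSome(ds, sample(classes, 1L), sample(props, 1L),
                                   sample(classes, 1L)))
  }
  randAgents <- function() sample(agents, sample(1:2, 1L))
  randPart <- function() sample(parts, 1L)

  justify <- function(a, depth) {
    if (depth > params$max_depth) return(invisible())
    nb <- sample(seq(params$branching[1], params$branching[2]), 1L)
    children <- vapply(seq_len(nb), function(k) {
      if (stats::runif(1) < params$p_reiterate)
        makeAssertion(ds, assertedPropositions(ds, a), randAgents(), randPart())
      else
        makeAssertion(ds, randProposition(), randAgents(), randPart(),
                      role = sample(c("factual", "conclusion", "unspecified"), 1L))
    }, "")
    if (length(children) >= 2L && stats::runif(1) < params$p_composite) {
      comp <- composeAssertions(ds, children)
      linkInference(ds, a, comp)
    } else {
      for (ch in children) linkInference(ds, a, ch)
    }
    for (ch in children) justify(ch, depth + 1L)
  }

  for (i in seq_len(params$n_conclusions)) {
    a <- makeAssertion(ds, randProposition(), randAgents(), randPart(),
                       role = "conclusion")
    if (params$max_depth >= 1L) justify(a, 1L)
  }
  ds
}
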