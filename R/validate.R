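## Structural validation of an evidence dataset.
##
## Violations are returned as diagnostic data, never raised: an
## open-world evidence record may legitimately be incomplete, so the
## caller decides what is fatal.

#' Diagnostic codes
#'
#' The closed set of codes \code{\link{validateDataset}} can emit, with
#' severities:
#' \describe{
#'   \item{DANGLING_PROPOSITION (error)}{an \code{asserts} target names no
#'     graph in the dataset}
#'   \item{NO_SUBJECT (error)}{assertion without \code{asserts}}
#'   \item{NO_AGENT (error)}{assertion without \code{is_assertion_made_by}}
#'   \item{SELF_PART (error)}{assertion among its own conjunctive parts}
#'   \item{DANGLING_REF (error)}{inference or conjunction link to a
#'     non-assertion}
#'   \item{SELF_INFERENCE (error)}{assertion directly inferred from itself}
#'   \item{BAD_INITIALS (error)}{agent initials empty or not uppercase
#'     letters}
#'   \item{EMPTY_CITATION (error)}{report without a non-empty citation
#'     label}
#'   \item{ORPHAN_PART (error)}{report part whose parent report is missing}
#'   \item{EMPTY_TEXT (error)}{text entity without a non-empty lexical
#'     structure}
#'   \item{CYCLE (warning)}{inference cycle (length > 1)}
#'   \item{NO_PROVENANCE (warning)}{assertion without a report link}
#'   \item{BAD_LABEL (warning)}{stored assertion label violating the
#'     "! P ! A" grammar}
#' }
#' @format character vector of codes.
#' @export
diagnosticCodes <- c("DANGLING_PROPOSITION", "NO_SUBJECT", "NO_AGENT",
                     "SELF_PART", "DANGLING_REF", "SELF_INFERENCE",
                     "BAD_INITIALS", "EMPTY_CITATION", "ORPHAN_PART",
                     "EMPTY_TEXT", "CYCLE", "NO_PROVENANCE", "BAD_LABEL")

diagnostic <- function(severity, code, message, subject) {
  data.frame(severity = severity, code = code, message = message,
             subject = subject, stringsAsFactors = FALSE)
}

noDiagnostics <- function() {
  data.frame(severity = character(), code = character(),
             message = character(), subject = character(),
             stringsAsFactors = FALSE)
}

#' Validate an evidence dataset
#'
#' Checks the structural invariants of the claim/provenance model and
#' returns all violations as a diagnostics data frame (columns
#' \code{severity}, \code{code}, \code{message}, \code{subject}); see
#' \code{\link{diagnosticCodes}} for the closed code set. An empty
#' dataset yields zero diagnostics; datasets produced by the package's
#' builders and fixtures validate with zero errors (warnings such as
#' missing provenance on curator claims are expected data).
#'
#' @param ds an \code{\linkS4class{EvidenceDataset}}.
#' @return diagnostics data frame, zero rows if nothing is wrong.
#' @export
validateDataset <- function(ds) {
  q <- quads(ds)
  voc <- vocabulary(ds)
  dft <- is.na(q$graph)
  out <- list(noDiagnostics())
  add <- function(severity, code, message, subject)
    out[[length(out) + 1L]] <<- diagnostic(severity, code, message, subject)

  graphs <- namedGraphs(ds)
  assertions <- unique(q$s[dft & q$p == RDF_TYPE & q$o == voc[["assertion"]]])
  agents <- unique(q$s[dft & q$p == RDF_TYPE & q$o == voc[["agent"]]])
  reports <- unique(q$s[dft & q$p == RDF_TYPE & q$o == voc[["report"]]])
  parts <- unique(q$s[dft & q$p == RDF_TYPE & q$o == voc[["report_part"]]])
  texts <- unique(q$s[dft & q$p == RDF_TYPE & q$o == voc[["text"]]])

  labelOf <- function(iri) {
    hit <- dft & q$s == iri & q$p == RDFS_LABEL & q$o_kind == "literal"
    if (any(hit)) q$o[hit][1] else NA_character_
  }

  for (a in assertions) {
    asserts <- q$o[dft & q$s == a & q$p == voc[["asserts"]]]
    madeBy <- q$o[dft & q$s == a & q$p == voc[["is_assertion_made_by"]]]
    madeIn <- q$o[dft & q$s == a & q$p == voc[["is_assertion_made_in"]]]
    pts <- q$o[dft & q$s == a & q$p == voc[["has_conjunctive_part"]]]
    idf <- q$o[dft & q$s == a & q$p == voc[["is_directly_inferred_from"]]]
    if (!length(asserts))
      add("error", "NO_SUBJECT", "assertion asserts no proposition", a)
    for (p in setdiff(asserts, graphs))
      add("error", "DANGLING_PROPOSITION",
          sprintf("asserted proposition <%s> names no graph", p), a)
    if (!length(madeBy))
      add("error", "NO_AGENT", "assertion has no asserting agent", a)
    if (a %in% pts)
      add("error", "SELF_PART", "assertion is its own conjunctive part", a)
    for (r in setdiff(c(pts, idf), assertions))
      add("error", "DANGLING_REF",
          sprintf("link target <%s> is not an assertion", r), a)
    if (a %in% idf)
      add("error", "SELF_INFERENCE", "assertion is inferred from itself", a)
    if (!length(madeIn))
      add("warning", "NO_PROVENANCE", "assertion has no report link", a)
    lab <- labelOf(a)
    if (!is.na(lab) &&
        !grepl("^! .+ ! .+$", lab))
      add("warning", "BAD_LABEL",
          sprintf("label does not follow the \"! P ! A\" grammar: %s", lab), a)
  }

  for (g in agents) {
    ini <- q$o[dft & q$s == g & q$p == voc[["has_initials"]] & q$o_kind == "literal"]
    if (!length(ini) || !grepl("^[A-Z]+$", ini[1]))
      add("error", "BAD_INITIALS",
          "agent initials missing or not uppercase letters", g)
  }
  for (r in reports) {
    cit <- labelOf(r)
    if (is.na(cit) || !nzchar(cit))
      add("error", "EMPTY_CITATION", "report has no citation label", r)
  }
  for (p in parts) {
    parent <- q$o[dft & q$s == p & q$p == voc[["is_part_of"]]]
    if (!length(parent) || !all(parent %in% reports))
      add("error", "ORPHAN_PART", "report part lacks an existing parent report", p)
  }
  for (tx in texts) {
    lex <- q$o[dft & q$s == tx & q$p == voc[["has_lexical_structure"]] &
                 q$o_kind == "literal"]
    if (!length(lex) || !nzchar(lex[1]))
      add("error", "EMPTY_TEXT", "text has no lexical structure", tx)
  }

  for (cyc in detectCycles(ds)) {
    if (length(cyc) > 1L)
      add("warning", "CYCLE",
          paste("inference cycle:", paste(cyc, collapse = " -> ")), cyc[1])
  }

  res <- do.call(rbind, out)
  res[order(res$severity, res$code, res$subject), , drop = FALSE]
}
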