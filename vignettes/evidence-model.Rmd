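---
title: "A claim-based model of scientific evidence: design and methods"
author: "semevid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A claim-based model of scientific evidence: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semevid)
```

## The model and its assumptions

`semevid` represents the evidence for a scientific finding as a network
of *claims*. The underlying assumptions are:

1. **Evidence relations hold between claims.** "This experiment is
   evidence for B" is treated as shorthand: what actually supports a
   conclusion is a set of accepted claims about the experiment — its
   inputs, outputs, the technique used, the assumptions made. The model
   therefore records premises and conclusions as assertions linked by
   `is_directly_inferred_from`, with a composite assertion (conjunctive
   parts) whenever several premises are used jointly.
2. **A claim, its subject and its wording are distinct things.** An
   assertion is a claim event with agents and (optionally) a report
   part as provenance; the *subject* — what is claimed — is a
   proposition stored as a named RDF graph; the verbatim wording, when
   kept, is a text entity with a lexical-structure literal. Because
   subjects are graphs with their own IRIs, claims about claims are
   ordinary claims, which yields stacked interpretation layers and
   alternative readings of the same data without special machinery.
3. **Open world.** A record is never "complete": assertions without
   provenance or without justification are legal data (flagged as
   warnings at most), and inference cycles are diagnosed rather than
   rejected — closure is defined as plain reachability, which is well
   defined on cyclic structures.

The vocabulary (classes `assertion`, `proposition`, `text`, `report`,
`report_part`, `agent`; properties `asserts`, `is_assertion_made_by`,
`is_assertion_made_in`, `is_directly_inferred_from`, `is_inferred_from`,
`has_conjunctive_part`, `has_lexical_structure`) lives under a
configurable namespace (the `rdo` prefix). Three auxiliary properties
are minted by this package because the narrative model requires the
links but does not name them: `is_expressed_as` (report part → text),
`is_part_of` (report part → report) and `has_initials` (agent →
initials literal). Assertion roles (`factual`, `assumption`,
`terminological`, `conclusion`, `interpretation`) are recorded with a
dataset-local annotation property (`ann:has_role`) rather than as core
vocabulary, since they are descriptive tags the query layer needs, not
part of the claim model itself.

## Storage and serialization

An `EvidenceDataset` is an RDF dataset: one default graph holding the
assertion/provenance structure and one named graph per proposition. TriG
is the normative exchange format; N-Quads is offered as a second
dialect. Since no R RDF library is part of this package's dependency
set, the TriG/N-Quads reader and writer are implemented here, for a
documented subset of TriG on input: prefix directives, graph blocks
(optional `GRAPH` keyword), `;`/`,` lists, `a`, IRIs, prefixed names,
blank-node labels, short and long string literals with language tags or
datatypes, and bare integer/decimal/boolean abbreviations. Anonymous
`[]` nodes and `(...)` collections are not accepted, blank-node labels
are scoped per graph, and nested named graphs cannot occur (TriG cannot
express them). Proposition graphs may refer to other propositions or
assertions by plain IRI — that is exactly how attribution subjects work.

Numerical/representation choices:

- Simple literals are normalized to `xsd:string` at construction (the
  RDF 1.1 identification), so round-trips compare cleanly.
- Serialization is deterministic: prefixes, graphs and triple lines are
  sorted, and blank nodes are relabelled canonically per graph by an
  iterated structural-signature refinement. Ties between signatures can
  only remain for automorphic blank nodes, for which any assignment
  yields identical bytes. Re-serializing a parsed document is therefore
  byte-stable, which the tests assert.
- Dataset isomorphism is decided per graph by a backtracking search for
  a blank-node bijection, pruned by the same signatures. Proposition
  graphs contain at most a handful of blank nodes (the existential
  pattern has four), so the search is effectively linear; the test
  suite cross-checks it against an exhaustive permutation search on
  small graphs.

## Subject formalization and labels

Three subject shapes are supported by the builders: a type declaration
(`individual rdf:type class`), a single property triple, and the
existential pattern for "some A related to some B" — an anonymous
individual typed by the intersection of A and an existential restriction,
expanded into the OWL 2 RDF mapping (intersection node, two-element RDF
list, restriction node with `owl:onProperty`/`owl:someValuesFrom`; ten
triples in total). Terminological statements such as "any GS-activity is
borne by some GS-enzyme" are stored as a single class-to-class property
triple; a Manchester `SubClassOf` axiom shape was considered and not
introduced, because nothing in the query layer needs it and the printed
labels of such statements are served equally well by the property shape.

Labels are derived from the graphs: `some A <relation> some B` for the
existential shape (property labels drop a leading `is_`/`has_` and
underscores when no `rdfs:label` is present, so `is_isolated_from`
prints as "isolated from"), `X Type: C` for type declarations (the
Manchester `Type` keyword; the exact rendering is this package's
choice), and `S P O` for property triples. Unsupported shapes fall back
to `"(complex subject)"` with a warning. Assertion labels are
`! P ! A` — proposition labels joined by `" AND "`, one space-separated
initials block — and are stored as `rdfs:label` while remaining
recomputable as a pure function of the dataset.

## Inference closure

The premises closure of an assertion is reachability over the expanded
relation *E* = `is_directly_inferred_from` ∪
(`is_directly_inferred_from` ∘ `has_conjunctive_part`): when a
conclusion rests on a composite, both the composite and its parts count
as premises. This materializes, as two explicit rules, what a DL
reasoner would derive from the transitivity of `is_inferred_from` and
the conjunction axioms; an explicit traversal was chosen because it is
dependency-free and directly testable against a brute-force oracle
(the property suites compare it with independent reachability
computations on hundreds of seeded networks). Derived provenance —
which reports, report parts and texts an assertion is based on — is the
union of the provenance links over the closure; the assertion's own
report is included by default (`includeSelf`), which is the reading
consistent with a reiterating review being "based on" both its own
report and the primary source. `materializeInferred()` writes the
closure and the derived `is_based_on_report`/`is_based_on_text`
relations into the named graph `urn:see:inferred` for export.

## Competency queries

Six query families demonstrate fitness of the representation; each has
a programmatic implementation and an equivalent SPARQL 1.1 rendering
(`emitSparql()`), and the agreement of the two routes on every fixture
and on seeded synthetic datasets is the central cross-check of the
query layer. Design choices:

- **Q1/Q2** match the existential pattern *structurally* over the OWL
  mapping triples inside asserted proposition graphs — no subclass
  reasoning over the entity class is attempted, and none is needed for
  the case study.
- **Q3 (independence)** declares two assertions on the same subject
  dependent when one lies in the other's premises closure; shared
  asserting agents are reported for every pair. In SPARQL the closure
  is the property path `(idf/part?)+`.
- **Q4/Q5 (experimental evidence)** require a *configurable* set of
  experimental-process classes (defaults: the assay and purification
  classes of the case-study vocabulary), because "experimental" is
  domain knowledge, not structure. Q5 pairs each technique-typing
  assertion in the closure with the observation it grounds, defined as
  the nearest conclusion-role assertion above it with no other
  conclusion-role assertion strictly between — a rule that both
  reproduces the worked example's printed pairs and stays expressible
  as a single SPARQL `FILTER NOT EXISTS`.
- **Q6 (account creator)** finds meta-assertions: assertions whose
  subject graph mentions one of the target assertions as subject or
  object of a triple.

## The case-study fixture and what it does not show

`buildGsCaseStudy()` reconstructs the glutamine-synthetase evidence
record: four agents, two reports, the conclusion chain A1 ← A2 ←
(A3, A4, A5) with the assay trail A3 ← (A6, A7, A8) ← (A9–A12) and role
tags (A9/A10 factual, A11 assumption, A12/A4 terminological), a curator
meta-assertion, the two curator-conclusion patterns and an alternative
interpretation reading the same data as evidence for GGT. Two parts are
reconstructions by symmetry rather than documented content: the
justification trail of A5 (assertions A15–A20: sample output of a
purification, rat livers as input, the TLM-purification typing, and
objective/terminological assertions mirroring A11/A12 — A13/A14 are
deliberately not invented) and the internal structure of the
alternative chain A41–A46. The report-part texts are illustrative
stand-ins, not quotations. The fixture's assertion and edge sets are
frozen by a golden test.

`genSynthetic()` produces seeded random evidence networks: per
conclusion a justification tree of configurable depth and branching,
with composites appearing with probability `p_composite` and premises
reiterating their conclusion's proposition with probability
`p_reiterate`; subjects are drawn uniformly from the three supported
shapes. Defaults (3 conclusions, depth 3, branching 1–3,
`p_composite` 0.4, `p_reiterate` 0.2, 4 agents, 3 reports) give
networks of a few dozen assertions — the scale of a hand-curated
evidence record; the property suites use 1–2 conclusions at depth 2
(≤ 30 assertions per network, a few hundred networks in total) so the
whole suite runs in about a minute. The generator emulates the
*structure* of evidence records — DAG-shaped argument networks,
reiteration, composition, mixed subject shapes — but not their content:
vocabulary is abstract (`class-1`, `prop-2`), agent overlap patterns are
uniform, and no cyclic or contradictory records are produced. Passing
property tests therefore demonstrates structural correctness (closure,
round-trip, validation behaviour), not robustness to semantically
malformed real-world curation.

## Validation

`validateDataset()` returns diagnostics as data, never exceptions, from
a closed code set (see `?diagnosticCodes`): referential errors
(dangling proposition graphs, missing agents/subjects, links to
non-assertions, self-inference, self-parts), provenance-entity errors
(initials grammar, empty citations, orphan report parts, empty texts),
and warnings for missing provenance, label-grammar violations and
inference cycles. Curator assertions legitimately lack report links, so
"zero errors" — not "zero diagnostics" — is the cleanliness criterion
for fixtures. Detection is monotone: adding triples can only add
diagnostics on the same entities, never silence one, which a property
test asserts under random triple injection.

## Known limitations

- The TriG reader covers the subset documented above, not the full
  grammar (no `[]`, no collections, no relative-IRI resolution beyond
  simple `@base` concatenation).
- One label per resource is assumed; multilingual labels are not
  selected by language.
- SPARQL execution is intentionally out of scope: `emitSparql()` emits
  standard SPARQL 1.1 text and any engine can run it (the test suite
  uses an external engine to verify agreement).
- Closure expands composites one level per inference step (*E* as
  defined); a composite nested directly inside another composite
  without an intervening inference link would not be expanded further —
  the builders never produce that shape.
- No OWL-DL consistency checking, SHACL export, or mapping to external
  biomedical ontologies.
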