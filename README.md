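# semevid — claim-based representation of scientific evidence

`semevid` is an R package for building, serializing, validating and
querying structured accounts of scientific evidence. It is aimed at
curators and knowledge engineers — for example in metabolic-network
reconstruction, where a modeller must record *why* an enzyme is believed
to act in a particular tissue — who need the full evidence trail behind a
claim to be computationally accessible, not a free-text note or a single
evidence code.

## The model

The representation is consistently **claim-based**. Its primitives:

- An **assertion** is a particular claim, made by particular **agents**
  on a particular occasion (in a **report part** of a **report**, whose
  wording may be kept as a **text**), that a proposition is true.
- A **proposition** is the subject of a claim — *what* is claimed. Each
  proposition is stored as an RDF **named graph** whose name is the
  proposition's IRI, so claim subjects are addressable and queryable
  (e.g. the graph `{ :assay-1 rdf:type :gamma_ghs_assay }` for "the assay
  performed was a γ-GHS assay"). Statements of the form "some A related
  to some B" are formalized as an anonymous instance of the OWL class
  `A and (related_to some B)`, expanded into its OWL 2 RDF mapping.
- Argumentative structure is recorded with
  `is_directly_inferred_from` links between assertions; joint use of
  several premises is made explicit by a **composite assertion** holding
  its premises via `has_conjunctive_part`. The transitive closure of
  this structure (`is_inferred_from`) is materialized by graph
  traversal.
- Because propositions are named graphs, an assertion can be *about*
  other assertions ("CB asserts that Tate et al. made assertion A10 in
  their 1972 report"), which supports arbitrarily many stacked layers of
  interpretation, curator conclusions drawn either from an author's
  statement or from the reported experimental evidence, and alternative
  interpretations of the same data.

Datasets are exchanged as TriG (default graph = assertion/provenance
structure; one named graph per proposition), with N-Quads as a second
dialect. Labels follow a fixed nomenclature: propositions render with
Manchester-syntax keywords ("some GS-enzyme isolated from some rat
liver"), assertions as `! P ! A` (proposition labels joined by `" AND "`,
then the asserting agents' initials).

## Worked example

The package ships a programmatic reconstruction of a two-article
case study: a 1985 review asserts that the enzyme glutamine synthetase
(GS, EC 6.3.1.2) was isolated from rat liver, reiterating the principal
conclusion of a 1972 primary report (protein sample purified from rat
livers, γ-glutamyl hydroxamate synthesis assay).

```r
library(semevid)

fx <- buildGsCaseStudy("full")
ds <- fx$dataset

assertionLabel(ds, fx$ids[["A1"]])
#> [1] "! some GS-enzyme isolated from some rat liver ! AM"

defs <- gsQueryDefaults(ds)
q1Locations(ds, defs$entityClass, defs$relation)
#> [1] "http://example.org/gsexample#rat_liver"

q3Independence(ds, fx$ids[["p1"]])
#> IndependenceReport for <http://example.org/gsexample#proposition-1>: NOT independent
#>   dependent: <http://example.org/gsexample#A1> inferred from <http://example.org/gsexample#A2>
#>   ...
#>   shared agents (...#A1|...#A2): http://example.org/gsexample#meister

length(premisesClosure(ds, fx$ids[["A1"]]))
#> [1] 21
basedOn(ds, fx$ids[["A1"]])$reports
#> [1] "http://example.org/gsexample#meister-1985"
#> [2] "http://example.org/gsexample#tate-1972"
```

The first call shows the label nomenclature; `q1Locations` answers
"which locations of GS have been asserted?" by structural matching of
the existential pattern in the proposition graphs; the independence
report shows that the two articles do **not** provide independent
observations (the review's claim is inferred from the primary report's,
and the author sets overlap); the closure of A1 spans the whole
21-assertion argumentative trail, grounded in both reports.

Every competency query also has a SPARQL 1.1 rendering
(`emitSparql(ds, "Q1", ...)`) that returns the same answers when run by
any SPARQL engine over the TriG serialization.

A command-line front end is installed as `exec/semevid`:

```sh
semevid build-example --variant full -o gs.trig
semevid query gs.trig --q Q1          # prints: rat liver
semevid validate gs.trig              # exit 0 (diagnostics to stderr)
semevid infer gs.trig --assertion http://example.org/gsexample#A1
semevid synth --seed 7 -o random.trig
```

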