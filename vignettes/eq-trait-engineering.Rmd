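---
title: "Engineering Entity-Quality trait ontologies with eqtraits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engineering Entity-Quality trait ontologies with eqtraits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtraits)
```

## The model

A *biological attribute* (trait) is a state-neutral characteristic of an
organism or one of its parts: "trochanter size", "blood lysine amount".
The Entity-Quality (EQ) pattern defines such a class as the conjunction
of a characteristic (the Q: "size", "amount", "morphology", drawn from a
characteristics hierarchy) with an existential restriction to the bearer
entity (the E: an anatomical structure, a chemical, possibly located in
a further entity):

```
blood lysine amount  ==  amount  and  (characteristic-of some (lysine and (part-of some blood)))
```

A *phenotypic abnormality* is a state of such a trait relative to a
reference: "Hypolysinemia" is an abnormal *decreased amount* of lysine
in blood. Because both shapes are ordinary OWL 2 EL class expressions
over shared reference vocabularies, a reasoner can compute, rather than
a curator assert, that every such state classifies under its
state-neutral trait, that "lysine in blood amount" sits under "amino
acid in blood amount" whenever the chemistry ontology says lysine is an
amino acid, and that a query like *morphology of anything that is part
of the cardiovascular system* retrieves "heart morphology" and "aorta
morphology" even though no such grouping class exists.

`eqtraits` implements this whole engineering cycle as a tested R
library plus a command-line interface: an EL expression/axiom data
model, format readers and writers, a design-pattern template compiler,
a saturation reasoner, relation-graph materialization, phenotype-trait
linking, lexical vocabulary alignment, and release quality control. All
test inputs are generated programmatically by the fixtures module.

## The supported logic fragment

Expressions are named classes, conjunctions and existential
restrictions; axioms are subclass axioms (complex left-hand sides —
GCIs — allowed), named-class equivalences, role hierarchy axioms and
role chains of length two. This is exactly the fragment the EQ patterns
and their mereological contracts need, and it keeps reasoning
polynomial. Parsers reject anything else (unions, negation, universal
restrictions, longer chains) with a pointed error rather than partially
supporting it: a corner-case-incomplete reasoner is worse than a loud
refusal, so beyond-EL input is a hard error throughout.

Expressions are canonicalized — conjunctions flattened, operands
deduplicated and sorted by a total lexicographic order on the rendered
form — so that syntactic identity of canonical keys implies logical
equivalence. That property (a congruence, verified by test) is what
lets the uniqueness check and the serializers work on strings.

## The reasoner

`classify()` is a consequence-based saturation reasoner. Input axioms
are first structurally normalized: every distinct complex subexpression
receives one fresh atom defined equivalent to it (a conservative
extension), leaving only primitive axiom forms

```
A1 n ... n An [= B        A [= some r. B        some r. A [= B
```

plus the role axioms. A worklist then applies the classic EL completion
rules — told/conjunction subsumption, existential introduction and
propagation, role-hierarchy closure, chain composition — to a fixpoint.
Design choices that matter:

* **Determinism.** The worklist is seeded in sorted order and every
  index is built in input order, so runs are reproducible and
  serialized outputs byte-identical.
* **Termination.** No rule creates an expression outside the input's
  subexpression closure; the atom set is fixed up front, so the number
  of derivable facts is quadratic in atoms per role, and a test asserts
  the atom bound.
* **Equivalences** are processed as the two subclass directions.
* **No bottom.** The fragment has no unsatisfiability, so "logical
  consistency" is operationalized structurally in QC (below).

Completeness is the risky property, so it is tested against an
independent oracle: `brute_force_subsumers()` re-derives the entailed
subsumption set by exhaustively re-applying every rule over the full
subexpression closure until nothing changes, implemented with boolean
matrices (told rules as column unions, existential propagation as a
matrix product) and sharing no saturation code with `classify()`. The
two agree exactly on 200 seeded random ontologies of up to 25 classes,
3 roles and 60 axioms — sizes chosen so the deliberately naive oracle
stays fast while still exercising GCIs, conjunctions, role hierarchies
and chains together. Monotonicity under axiom addition is tested on
seeded prefix pairs.

`entails()` and `query_named_subclasses()` reduce to classification by
introducing fresh query classes equivalent to the queried expressions;
query results exclude obsoleted classes.

## The pattern compiler

A pattern is a YAML document: an ordered variable map (name → range
class), printf-style text templates (label, definition, synonyms) whose
`%s` slots are filled with reference-term labels in the order of each
template's variable list, one `equivalent_to` logic schema and optional
GCI schemas in a Manchester-like mini syntax, and the roles those
schemas use. A filler table binds each variable to a reference term id
per defined class. Choices:

* **Label word order lives in the pattern**, not in a global heuristic:
  `"%s %s"` over (entity, attribute) yields "trochanter size";
  the chemical pattern's (location, chemical, attribute) order yields
  "blood glucose amount". The default definition wording is "The
  *attribute* of *entity*.", overridable per pattern.
* **Range checks are semantic.** A binding is valid when the reasoner
  classifies it under the variable's range in the references — never by
  id-prefix string matching. The basic entity-attribute pattern leaves
  its entity range at `owl:Thing` because its entities may be chemicals
  or anatomical structures; the chemical-in-entity pattern constrains
  chemical and location properly.
* **The GCI schema** instantiated per compiled row is
  `Q n (characteristic-of some (part-of some E)) [= part-of some (Q n (characteristic-of some E))`.
  This is the weakest EL schema we found that provably yields the
  desired mereological propagation — "ulna size" *part-of* "forelimb
  skeleton size" whenever the anatomy asserts ulna *part-of* forelimb
  skeleton — without ever collapsing part and whole into a subclass
  relation ("eye size" must relate to "head size" mereologically, not
  taxonomically). Both halves are tested.
* **Compiled fragments assert no subclass links between compiled
  terms** (tested by scanning); the polyhierarchy is entirely
  reasoner-derived.
* Errors aggregate: a bad table reports every offending row and any
  duplicate defined-class ids with both row numbers, instead of failing
  on the first.

`derive_trait_candidates()` inverts the abnormality shape: it
decomposes phenotype equivalences of the form *state + bearer +
abnormal modifier*, lifts the state characteristic to its nearest
attribute-level ancestor (the `attribute_slim` subset marks attribute
rank: "decreased amount" proposes "amount"), and emits needs-curation
filler rows; classes with complex bearers or no decomposable definition
go to a skipped report rather than erroring. Identical proposals from
several states are merged with their sources recorded.

## Relation graph

`materialize()` converts a classified ontology into entailed node-edge
triples: an edge `(C, r, D)` for every entailed `C [= some r. D` over
named classes, read directly off the saturation's derived role
relations (whose completeness the canonical-model argument guarantees),
plus `is_a` edges forming the transitive reduction of the taxonomy.
Complex fillers are traversed, never surfaced. Reflexive role edges are
suppressed by default (flag-enabled) as downstream noise. Each role
edge carries a redundancy flag — dominated by a strictly deeper object
or an edge inherited from a strict superclass — and the non-redundant
core regenerates the full set exactly under hierarchy closure (tested,
and every emitted edge is re-verified by an independent `entails()`
call). Both the full and the non-redundant sets are exposed, since
downstream consumers legitimately want either.

## Phenotype-trait linking

`link_phenotypes()` merges the phenotype ontology with the trait
release, classifies, and emits one SSSOM row per phenotype class and
non-redundant (deepest) trait superclass, with the full closure
available by flag. Two decisions were genuinely open:

* **Predicate:** rows use `skos:broadMatch` — a phenotype is a
  narrower, state-qualified concept than its state-neutral attribute,
  and broadMatch preserves that direction within the SSSOM predicate
  vocabulary. Justification is `semapv:LogicalReasoning`, cleanly
  separating reasoner-derived rows from the lexical pipeline's
  `semapv:LexicalMatching`.
* **Counting:** link counts are taken on the materialized mapping set,
  not the axiom list, and default to non-redundant rows — emitting the
  closure would flood output with links to very general attributes.
  Both figures are computable here.

Unmapped phenotype classes are reported; the summary counts classes
under any trait, total classes, and links. Extraction is idempotent on
its own merged output (tested).

## Lexical matching

`normalize_label()` lowercases, strips punctuation, tokenizes on
whitespace and removes stop words; the default stop list is
`{measurement, measurements, trait, traits}` — the boilerplate words of
external measurement vocabularies plus plurals, and nothing more. No
further normalization (stemming, synonym expansion) is invented; what
you normalize is what you match. Exact matching runs before
decomposition (Match before Sync), uses labels and EXACT synonyms only,
and maps each external term to at most one trait — an ambiguous
normalized form yields no match plus an explicit ambiguity note, never
an arbitrary pick. Matching targets only the compiled (definition-
bearing) terms of a release, so reference classes merged into it are
not offered as trait matches.

Decomposition scans the normalized label for contiguous token runs
equal to a reference term's normalized label or EXACT synonym,
honouring the configured reference order; conflicts resolve
longest-match, leftmost, non-overlapping, earlier ontology first.
Matched terms fill pattern variables by semantic range, and the pattern
filling the most slots wins (ties: configured pattern order). Curator
decisions travel in a plain TSV review file — reproducible curation
artifacts, no interactive state; accepted exact matches become SSSOM
rows, accepted decompositions become filler rows with freshly minted
sequential ids (7-digit zero-padded; source-tagged ids such as a
`VT`-prefixed local are preserved verbatim wherever they enter and are
never re-minted).

## Quality control

`run_qc()` implements the release gate: `ROOT_COVERAGE` (every live
defined term under the root attribute), `UNIQUENESS` (no two distinct
live classes entailed equivalent), `CONSISTENCY`, `OBSOLETION`
(deprecated terms need the "obsolete " label prefix and must have shed
all logical axioms; a replacement pointer is preserved), and
`DANGLING_REF` (axioms referencing undeclared ids). Since EL cannot
express unsatisfiability, `CONSISTENCY` is the structural reading:
an equivalence group produced by an *asserted* subsumption cycle among
defined terms — curator error in the told axioms — is distinguished
from `UNIQUENESS`, which flags equivalence arising from duplicate
definitions. Each of the five seeded defect generators triggers exactly
its check on an otherwise clean release, and the clean fixture release
is empty under all checks. The CLI exits 0 on clean, 1 on any QC error,
2 on input/parse errors — a stable continuous-integration contract.

## Fixtures: what they emulate and what they do not

`build_fixture_bundle()` generates, fully deterministically, a mini
anatomy (eye in head, ulna in forelimb skeleton, heart and aorta in the
cardiovascular system, blood, trochanter, brain ventricle), a mini
chemistry (lysine under amino acid under chemical entity; glucose; a
chemical-role branch), a characteristics hierarchy whose attribute-level
terms carry the `attribute_slim` marker over their state-level children,
the role axioms (characteristic-of ∘ part-of ⊑ characteristic-of-part-of;
part-of transitivity), a phenotype ontology with eight EQ-defined
abnormality classes (the lysine pair, three head-size states, a
ventricle-size state, a glucose state, a heart-morphology state) plus
two undecomposable classes, four patterns and three filler tables, and
a ten-term external vocabulary engineered to exercise every match kind.

These fixtures emulate the *shapes* that matter — part-of chains,
chemical subsumption feeding trait subsumption, attribute/state rank,
decomposable and undecomposable definitions — at desk scale. They do
not emulate: real-ontology size (thousands of classes and deeper
hierarchies), lexical messiness of real labels and synonyms, beyond-EL
axioms present in some real imports (which this toolkit rejects by
design), cross-species anatomy subtleties, or curation history. Passing
tests therefore demonstrate correctness of the mechanisms, not recall
or precision figures on any real vocabulary.

Identifiers in the fixtures imitate the look of the real namespaces for
readability, but every ontology here is a small synthetic hand-built
fragment, not an extract of the corresponding resource.

## Numerical and degenerate-input choices

* Random test ontologies: up to 25 classes, 3 roles, 60 axioms; 200
  seeds for the oracle sweep (about 15 s), 40 for the quick screen.
  These sizes keep the matrix oracle exact and fast while covering all
  axiom forms; the generator draws every existential filler from the
  declared class set so the closure stays finite, and it restores the
  session RNG state.
* Empty inputs are legal everywhere: empty documents parse to empty
  ontologies, empty ontologies classify to empty results, an empty role
  set materializes is_a edges only, an all-stop-word label normalizes
  to zero tokens and is reported as such.
* Ties: canonical sorting breaks all expression-order ties; candidate
  ambiguity is surfaced, not resolved; equivalence groups are
  represented by their lexicographically first member.
* Absent SSSOM confidence serializes as an empty cell, never `0`.

## Known limitations

* The OBO writer covers only the subset whose semantics the flat-file
  format can express; GCIs and nested fillers must use functional
  syntax (the writer says so rather than dropping axioms).
* No datatype properties, individuals, annotations beyond the term
  record fields, RDF/XML or Manchester file syntax, or SPARQL.
* Reasoning is batch, not incremental; each query classification
  re-saturates. At the intended desk scale this is milliseconds.
* The ten production trait templates of a real release exist only in
  their upstream repositories; the four patterns here are
  representative of the mechanics (basic entity-attribute,
  chemical-in-entity, role-based, abnormality), not byte-identical
  copies.
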