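# eqtraits

Entity-Quality trait ontology engineering in R, for ontology engineers
and phenomics data wranglers who need to build, classify, link and
quality-control trait vocabularies without a Java OWL stack.

A *biological attribute* (trait) is a state-neutral characteristic of an
organism or one of its parts. The Entity-Quality (EQ) pattern defines it
as a characteristic Q restricted existentially to a bearer entity E:

```
blood lysine amount == amount and
    (characteristic-of some (lysine and (part-of some blood)))
```

Phenotypic abnormalities are *states* of such traits ("Hypolysinemia" is
an abnormal decreased amount of lysine in blood). With both shapes
expressed in the OWL 2 EL fragment over shared reference ontologies, an
EL reasoner derives the entire trait polyhierarchy, the links from
abnormality classes to their state-neutral traits, and part-whole
relation edges between traits — nothing is hand-asserted.

The package provides:

* **core model** — CURIEs/PURLs, canonicalized EL class expressions,
  axioms (GCIs, equivalences, role hierarchies, 2-step role chains),
  an ontology container with tibble views;
* **I/O** — OBO flat-file subset, OWL functional-syntax subset (the
  canonical logical format; byte-deterministic writer), SSSOM TSV,
  OBO Graph JSON, relation-edge TSV;
* **pattern compiler** — DOS-DP-style YAML templates + TSV filler
  tables → defined classes with generated labels/definitions/synonyms,
  equivalence axioms and mereology-propagating GCIs; plus EQ
  decomposition of phenotype definitions into proposed filler rows;
* **reasoner** — consequence-based EL saturation (`classify()`,
  `entails()`, `query_named_subclasses()`), validated against an
  independent brute-force matrix oracle on 200 seeded random
  ontologies;
* **relation graph** — entailed named-class edges with redundancy
  flags, non-redundant core, closure reconstruction;
* **linker** — merge → reason → materialize → extract SSSOM mappings
  from phenotype ontologies to trait terms;
* **matcher** — normalization-based exact matching plus
  reference-ontology decomposition of external vocabularies, with a
  TSV review round-trip;
* **qc** — root coverage, uniqueness, consistency, obsoletion
  conventions, dangling references; CLI exit codes 0/1/2;
* **fixtures** — deterministic generators for every test input,
  including seeded random EL ontologies and five release-defect
  injectors;
* **CLI** — `inst/cli/eqtraits.R` with `compile`, `classify`, `query`,
  `relation-graph`, `link`, `match`, `apply-review`, `qc`, `fixtures`
  and a composed `run` subcommand.

## Worked example

```r
library(eqtraits)

bundle  <- build_fixture_bundle()     # mini anatomy/chemistry/characteristics + patterns
release <- fixture_release(bundle)    # compile all filler tables against the references
result  <- classify(release)
result
#> <classification> 40 classes, 156 subsumptions, 0 equivalence group(s)

# the reasoner classifies "blood lysine amount" (OBA:2020005) under
# "blood amino acid amount" (OBA:1000008) purely from lysine [= amino acid:
tidy(result) |> dplyr::filter(class == "OBA:2020005")
#> # A tibble: 4 × 2
#>   class       subsumer
#>   <chr>       <chr>
#> 1 OBA:2020005 OBA:0000001
#> 2 OBA:2020005 OBA:1000008
#> 3 OBA:2020005 PATO:0000001
#> 4 OBA:2020005 PATO:0000070

# DL query: morphology of parts of the cardiovascular system
query_named_subclasses(release,
  "PATO:0000051 and (RO:0002314 some UBERON:0004535)")
#> [1] "OBA:1000005" "OBA:1000006"      # heart morphology, aorta morphology

# phenotype -> trait links ("Hypolysinemia" lands under "blood lysine amount")
link <- link_phenotypes(release, bundle$mini_phenotype)
link
#> <phenotype-trait links> 8 mapping(s); 8/11 phenotype class(es) under a trait; 3 unmapped
glance(link)
#> # A tibble: 1 × 4
#>   links classes_under_root n_phenotypes n_unmapped
#> 1     8                  8           11          3

# GCI-derived mereology: "ulna size" is part of "forelimb skeleton size",
# never its subclass
materialize(release, result, roles = "BFO:0000050") |>
  dplyr::filter(subject == "OBA:1000003")
#> # A tibble: 5 × 4
#>   subject     predicate   object       redundant
#> 1 OBA:1000003 BFO:0000050 OBA:0000001  TRUE
#> 2 OBA:1000003 BFO:0000050 OBA:1000004  FALSE
#> 3 OBA:1000003 BFO:0000050 PATO:0000001 TRUE
#> 4 OBA:1000003 BFO:0000050 PATO:0000117 TRUE
#> 5 OBA:1000003 is_a        PATO:0000117 FALSE
```

The 8 mappings are SSSOM rows (`skos:broadMatch`,
`semapv:LogicalReasoning`); the 3 unmapped classes are the phenotype
root and the two fixture classes that carry no EQ definition. See
`vignettes/eq-trait-engineering.Rmd` for the model, the completion
rules, and every design decision.

## Command line

```sh
Rscript inst/cli/eqtraits.R fixtures --out fx/       # write the fixture workspace
Rscript inst/cli/eqtraits.R run --config fx/run.yaml # compile→classify→graph→link→qc
Rscript inst/cli/eqtraits.R query --input fx/out/compiled.ofn \
  --expression 'PATO:0000051 and (RO:0002314 some UBERON:0004535)'
```

Exit codes: 0 clean, 1 QC error, 2 input/parse error.

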