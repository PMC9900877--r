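Package: eqtraits
Title: Entity-Quality Trait Ontology Engineering Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and maintaining Entity-Quality (EQ) trait
    ontologies in the OWL 2 EL fragment. Compiles design-pattern templates
    (YAML) plus filler tables (TSV) into defined trait classes with generated
    labels, definitions and General Concept Inclusion axioms; classifies the
    result with a consequence-based EL saturation reasoner supporting
    conjunction, existential restrictions, GCIs, role hierarchies and role
    chains; materializes the entailed class graph as relation edges; infers
    links from EQ-axiomatised phenotypic-abnormality ontologies to trait
    terms and exports them as SSSOM mappings; aligns external trait
    vocabularies by normalization-based lexical matching and EQ
    decomposition; and runs release quality-control checks (root coverage,
    uniqueness, obsoletion conventions, dangling references, consistency).
    Includes deterministic fixture generators, a brute-force reasoning
    oracle, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
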