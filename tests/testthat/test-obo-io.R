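test_that("OBO term stanzas parse with standard OWL semantics", {
  txt <- c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: UBERON:0001424",
    "name: ulna",
    "is_a: UBERON:0001062 ! anatomical entity",
    "relationship: BFO:0000050 UBERON:0001440",
    "",
    "[Term]",
    "id: UBERON:0001440",
    "name: forelimb skeleton",
    'def: "The skeleton of the forelimb." []',
    'synonym: "forelimb skeletal system" EXACT []'
  )
  ont <- parse_obo(txt)
  expect_setequal(names(ont$terms), c("UBERON:0001424", "UBERON:0001440"))
  keys <- vapply(ont$axioms, eqtraits:::axiom_key, character(1))
  expect_true("SubClassOf(UBERON:0001424 UBERON:0001062)" %in% keys)
  expect_true(
    "SubClassOf(UBERON:0001424 (BFO:0000050 some UBERON:0001440))" %in% keys
  )
  fs <- ont$terms[["UBERON:0001440"]]
  expect_equal(fs$definition, "The skeleton of the forelimb.")
  expect_equal(fs$synonyms[[1]]$scope, "EXACT")
})

test_that("intersection_of stanzas become a single equivalence axiom", {
  txt <- c(
    "[Term]", "id: X:1", "name: head size",
    "intersection_of: PATO:0000117",
    "intersection_of: RO:0000052 UBERON:0000033"
  )
  ont <- parse_obo(txt)
  eqs <- Filter(function(a) a$type == "equiv", ont$axioms)
  expect_length(eqs, 1L)
  expect_equal(
    expr_key(eqs[[1]]$expr),
    "((RO:0000052 some UBERON:0000033) and PATO:0000117)"
  )
  expect_error(parse_obo(c("[Term]", "id: X:1", "intersection_of: PATO:0000117")),
               "single intersection_of")
})

test_that("obsolete stanzas carry no axioms and reject logical tags", {
  ont <- parse_obo(c(
    "[Term]", "id: X:1", "name: obsolete head size",
    "is_obsolete: true", "replaced_by: X:2"
  ))
  expect_true(ont$terms[["X:1"]]$deprecated)
  expect_equal(ont$terms[["X:1"]]$replaced_by, "X:2")
  expect_length(ont$axioms, 0L)

  expect_error(
    parse_obo(c("[Term]", "id: X:1", "is_obsolete: true", "is_a: X:2")),
    "obsolete term X:1 carries logical tag"
  )
})

test_that("empty documents and unknown tags are handled gracefully", {
  expect_length(parse_obo("")$terms, 0L)
  expect_warning(
    parse_obo(c("[Term]", "id: X:1", "name: a", "mystery_tag: zzz")),
    "mystery_tag"
  )
})

test_that("typedef stanzas yield role hierarchy and chain axioms", {
  ont <- parse_obo(c(
    "[Typedef]", "id: BFO:0000050", "name: part of", "is_transitive: true",
    "",
    "[Typedef]", "id: RO:0002314", "name: characteristic of part of",
    "holds_over_chain: RO:0000052 BFO:0000050",
    "",
    "[Typedef]", "id: RO:0000052", "name: characteristic of",
    "is_a: RO:0002314"
  ))
  keys <- vapply(ont$axioms, eqtraits:::axiom_key, character(1))
  expect_true(
    "SubObjectPropertyOf(ObjectPropertyChain(BFO:0000050 BFO:0000050) BFO:0000050)" %in% keys
  )
  expect_true(
    "SubObjectPropertyOf(ObjectPropertyChain(RO:0000052 BFO:0000050) RO:0002314)" %in% keys
  )
  expect_true("SubObjectPropertyOf(RO:0000052 RO:0002314)" %in% keys)
})

test_that("functional syntax round-trips preserve canonical axiom sets", {
  b <- fx_bundle()
  for (ont in list(b$mini_anatomy, b$mini_chemical, b$mini_characteristics,
                   b$mini_phenotype, b$relations, fx_release())) {
    txt <- write_functional_syntax(ont)
    back <- parse_functional_syntax(txt)
    expect_identical(
      eqtraits:::canonical_axiom_set(back),
      eqtraits:::canonical_axiom_set(ont)
    )
    # term metadata survives too
    expect_identical(sort(as.character(names(back$terms))),
                     sort(as.character(names(ont$terms))))
    for (id in names(ont$terms)) {
      expect_identical(back$terms[[id]]$label, ont$terms[[id]]$label)
      expect_identical(back$terms[[id]]$deprecated, ont$terms[[id]]$deprecated)
    }
  }
})

test_that("functional syntax writer is deterministic and parser rejects non-EL", {
  rel <- fx_release()
  expect_identical(write_functional_syntax(rel), write_functional_syntax(rel))

  empty <- write_functional_syntax(new_ontology())
  expect_match(empty, "Ontology\\(")
  expect_length(parse_functional_syntax(empty)$axioms, 0L)

  # GCIs (complex left sides) parse
  gci <- parse_functional_syntax(paste(
    "Ontology(",
    "SubClassOf(ObjectIntersectionOf(X:A ObjectSomeValuesFrom(r:1 X:B)) X:C)",
    ")", sep = "\n"
  ))
  expect_equal(gci$axioms[[1]]$sub$type, "and")

  expect_error(
    parse_functional_syntax("Ontology(\nSubClassOf(ObjectUnionOf(X:A X:B) X:C)\n)"),
    "unsupported construct 'ObjectUnionOf'"
  )
})

test_that("OBO writing round-trips the reference fixtures", {
  b <- fx_bundle()
  for (ont in list(b$mini_anatomy, b$mini_chemical, b$mini_characteristics)) {
    back <- parse_obo(write_obo(ont))
    expect_identical(
      eqtraits:::canonical_axiom_set(back),
      eqtraits:::canonical_axiom_set(ont)
    )
  }
  # the release holds GCIs, which OBO cannot express
  expect_error(write_obo(fx_release()), "GCI")
})

test_that("SSSOM output has fixed columns, metadata header and empty-not-zero confidence", {
  empty <- write_sssom(eqtraits:::empty_sssom(), metadata = list(license = "CC0"))
  lines <- strsplit(empty, "\n")[[1]]
  expect_equal(lines[1], "# license: CC0")
  expect_equal(
    lines[2],
    paste("subject_id", "subject_label", "predicate_id", "object_id",
          "object_label", "mapping_justification", "confidence", sep = "\t")
  )
  expect_length(lines, 2L)

  link <- fx_link()
  txt <- write_sssom(link$mappings)
  data_lines <- setdiff(strsplit(txt, "\n")[[1]], "")[-1]
  expect_length(data_lines, nrow(link$mappings))
  # absent confidence serializes as an empty trailing cell, not "0"
  expect_true(all(grepl("\t$", paste0(data_lines, ""))))
  expect_false(any(grepl("\t0$", data_lines)))

  expect_error(
    sssom_row("A:1", "a", "skos:exactMatch", "B:1", "b", "semapv:Guesswork"),
    "unsupported mapping_justification"
  )
})

test_that("OBO Graph JSON is deterministic with expected nodes and edges", {
  expect_equal(
    as.character(jsonlite::minify(write_obograph_json(new_ontology()))),
    '{"nodes":[],"edges":[]}'
  )
  b <- fx_bundle()
  doc <- jsonlite::fromJSON(
    write_obograph_json(b$mini_anatomy), simplifyVector = FALSE
  )
  expect_length(doc$nodes, length(b$mini_anatomy$terms))

  rel <- fx_release()
  edges <- materialize(rel, fx_result(), roles = "BFO:0000050")
  doc2 <- jsonlite::fromJSON(
    write_obograph_json(rel, edges), simplifyVector = FALSE
  )
  purls <- vapply(doc2$edges, function(e) paste(e$sub, e$pred, e$obj), character(1))
  expect_true(
    paste(
      expand_curie(TRAIT[["ulna size"]]),
      expand_curie("BFO:0000050"),
      expand_curie(TRAIT[["forelimb skeleton size"]])
    ) %in% purls
  )
})
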