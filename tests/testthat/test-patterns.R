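test_that("pattern YAML loads with ordered vars and validated templates", {
  p <- fx_bundle()$patterns$entity_attribute
  expect_s3_class(p, "eq_pattern")
  expect_equal(names(p$vars), c("attribute", "entity"))
  expect_length(p$gci_templates, 1L)

  bad_arity <- "
pattern_id: broken
vars:
  attribute: PATO:0000001
  entity: owl:Thing
name:
  text: \"%s %s %s\"
  vars: [entity, attribute]
equivalent_to:
  text: \"%s and (RO:0000052 some %s)\"
  vars: [attribute, entity]
"
  expect_error(load_pattern(bad_arity), "3 slot\\(s\\) but 2 var")

  undeclared <- "
pattern_id: broken2
vars:
  attribute: PATO:0000001
name:
  text: \"%s %s\"
  vars: [attribute, entity]
equivalent_to:
  text: \"%s\"
  vars: [attribute]
"
  expect_error(load_pattern(undeclared), "undeclared var\\(s\\) entity")
})

test_that("entity-attribute rows compile to generated text and an equivalence", {
  b <- fx_bundle()
  refs <- fx_refs()
  out <- compile_row(
    b$patterns$entity_attribute,
    list(defined_class = "OBA:0002360", attribute = "PATO:0000117",
         entity = "UBERON:0000980"),
    refs
  )
  expect_equal(out$term$label, "trochanter size")
  expect_equal(out$term$definition, "The size of trochanter.")
  expect_equal(out$axioms[[1]]$type, "equiv")
  expect_equal(
    expr_key(out$axioms[[1]]$expr),
    "((RO:0000052 some UBERON:0000980) and PATO:0000117)"
  )
  # one GCI instantiated from the pattern schema
  expect_equal(out$axioms[[2]]$type, "subclass")
  expect_false(eqtraits:::expr_is_named(out$axioms[[2]]$sub))
})

test_that("chemical-in-entity rows nest the location inside the bearer", {
  b <- fx_bundle()
  out <- compile_row(
    b$patterns$chemical_in_entity_attribute,
    list(defined_class = "OBA:VT0000188", attribute = "PATO:0000070",
         chemical = "CHEBI:17234", location = "UBERON:0000178"),
    fx_refs()
  )
  expect_equal(out$term$label, "blood glucose amount")
  expect_equal(
    expr_key(out$axioms[[1]]$expr),
    "((RO:0000052 some ((BFO:0000050 some UBERON:0000178) and CHEBI:17234)) and PATO:0000070)"
  )
  # generated exact synonym mirrors the in-blood phrasing
  expect_equal(out$term$synonyms[[1]]$text, "glucose in blood amount")
})

test_that("role-based rows use the has-role relation", {
  b <- fx_bundle()
  out <- compile_row(
    b$patterns$role_attribute,
    list(defined_class = "OBA:2050092", attribute = "PATO:0000070",
         role = "CHEBI:9000001"),
    fx_refs()
  )
  expect_equal(out$term$label, "serum metabolite amount")
  expect_match(expr_key(out$axioms[[1]]$expr), "RO:0000087 some CHEBI:9000001")
})

test_that("rows with unknown or out-of-range fillers are rejected", {
  b <- fx_bundle()
  refs <- fx_refs()
  expect_error(
    compile_row(b$patterns$entity_attribute,
                list(defined_class = "OBA:9", attribute = "PATO:0000117",
                     entity = "UBERON:404"),
                refs),
    "UBERON:404.*not in references"
  )
  # an anatomical entity is not a characteristic: range check is semantic
  expect_error(
    compile_row(b$patterns$entity_attribute,
                list(defined_class = "OBA:9", attribute = "UBERON:0000033",
                     entity = "UBERON:0000980"),
                refs),
    "not classified under its range PATO:0000001"
  )
})

test_that("table compilation counts terms and aggregates errors", {
  b <- fx_bundle()
  refs <- fx_refs()
  frag <- compile_table(b$patterns$entity_attribute,
                        b$tables$entity_attribute, refs)
  expect_length(frag$terms, nrow(b$tables$entity_attribute))
  eqs <- Filter(function(a) a$type == "equiv", frag$axioms)
  gcis <- Filter(function(a) a$type == "subclass" &&
                   !eqtraits:::expr_is_named(a$sub), frag$axioms)
  expect_length(eqs, 9L)
  expect_length(gcis, 9L)

  # duplicates are reported with both row numbers; other bad rows too
  tbl <- b$tables$entity_attribute[c(1, 2, 3, 1), ]
  err <- tryCatch(
    compile_table(b$patterns$entity_attribute, tbl, refs),
    error = conditionMessage
  )
  expect_match(err, "duplicate defined_class OBA:0002360 in rows 1 and 4")

  tbl2 <- b$tables$entity_attribute[1:3, ]
  tbl2$entity[2] <- "UBERON:404"
  tbl2$attribute[3] <- "UBERON:0000033"
  err2 <- tryCatch(
    compile_table(b$patterns$entity_attribute, tbl2, refs),
    error = conditionMessage
  )
  expect_match(err2, "row 2")
  expect_match(err2, "row 3")
})

test_that("compiled fragments never assert subsumption between compiled terms", {
  b <- fx_bundle()
  refs <- fx_refs()
  for (nm in names(b$tables)) {
    frag <- compile_table(b$patterns[[nm]], b$tables[[nm]], refs)
    compiled <- names(frag$terms)
    asserted <- Filter(function(ax) {
      ax$type == "subclass" &&
        eqtraits:::expr_is_named(ax$sub) && eqtraits:::expr_is_named(ax$sup) &&
        ax$sub$id %in% compiled && ax$sup$id %in% compiled
    }, frag$axioms)
    expect_length(asserted, 0L)
  }
})

test_that("every part-of pair of compiled traits satisfies the GCI contract", {
  b <- fx_bundle()
  rel <- fx_release()
  res <- fx_result()
  tbl <- b$tables$entity_attribute
  # entity-level part-of premises present in the fixture anatomy
  part_of_pairs <- list(
    c("UBERON:0000970", "UBERON:0000033"),  # eye in head
    c("UBERON:0001424", "UBERON:0001440")   # ulna in forelimb skeleton
  )
  for (pair in part_of_pairs) {
    for (q in unique(tbl$attribute)) {
      t_sub <- tbl$defined_class[tbl$entity == pair[1] & tbl$attribute == q]
      t_sup <- tbl$defined_class[tbl$entity == pair[2] & tbl$attribute == q]
      if (!length(t_sub) || !length(t_sup)) next
      expect_true(
        entails(rel, c_named(t_sub), c_some("BFO:0000050", t_sup)),
        info = paste(t_sub, "part-of", t_sup)
      )
      expect_false(t_sup %in% res$subsumers[[t_sub]])
    }
  }
})

test_that("text generation is total over the compiled release", {
  rel <- fx_release()
  compiled <- names(eqtraits:::ont_equiv_map(rel))
  for (id in compiled) {
    expect_true(nzchar(rel$terms[[id]]$label), info = id)
    expect_true(nzchar(rel$terms[[id]]$definition), info = id)
  }
})

test_that("phenotype definitions decompose into reviewed filler proposals", {
  b <- fx_bundle()
  out <- derive_trait_candidates(b$mini_phenotype, b$mini_characteristics)
  # five named-bearer abnormality classes collapse to three distinct
  # attribute/entity proposals
  expect_equal(nrow(out$rows), 3L)
  expect_true(all(out$rows$needs_curation))
  got <- paste(out$rows$attribute, out$rows$entity)
  expect_setequal(got, c(
    "PATO:0000117 UBERON:0000033",   # head size states (3 sources)
    "PATO:0000117 UBERON:0004086",   # ventriculomegaly
    "PATO:0000051 UBERON:0000948"    # heart morphology
  ))
  head_row <- out$rows[out$rows$entity == "UBERON:0000033", ]
  expect_equal(
    head_row$source_phenotypes,
    "PHEN:0000003|PHEN:0000004|PHEN:0000005"
  )
  # the state quality maps up to its attribute-level ancestor: the
  # decreased-size state proposes plain "size"
  expect_false("PATO:0000587" %in% out$rows$attribute)

  # undecomposable classes are reported, not errors
  expect_true(all(c("PHEN:0000009", "PHEN:0000010") %in% out$skipped$id))
  expect_true("PHEN:0000001" %in% out$skipped$id) # complex bearer
  n_sources <- length(unlist(strsplit(out$rows$source_phenotypes, "|", fixed = TRUE)))
  expect_equal(n_sources + nrow(out$skipped), length(b$mini_phenotype$terms))
})
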