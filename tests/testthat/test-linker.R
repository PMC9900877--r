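test_that("EQ-defined abnormality classes map to their state-neutral traits", {
  link <- fx_link()
  m <- link$mappings
  expected <- c(
    "PHEN:0000001" = TRAIT[["blood lysine amount"]],     # Hypolysinemia
    "PHEN:0000002" = TRAIT[["blood lysine amount"]],
    "PHEN:0000003" = TRAIT[["head size"]],
    "PHEN:0000004" = TRAIT[["head size"]],
    "PHEN:0000005" = TRAIT[["head size"]],
    "PHEN:0000006" = TRAIT[["brain ventricle size"]],    # Ventriculomegaly
    "PHEN:0000007" = TRAIT[["blood glucose amount"]],
    "PHEN:0000008" = TRAIT[["heart morphology"]]
  )
  expect_equal(nrow(m), length(expected))
  for (p in names(expected)) {
    expect_equal(m$object_id[m$subject_id == p], unname(expected[[p]]), info = p)
  }
  expect_true(all(m$predicate_id == "skos:broadMatch"))
  expect_true(all(m$mapping_justification == "semapv:LogicalReasoning"))
})

test_that("classes without EQ definitions end up unmapped", {
  link <- fx_link()
  expect_true(all(c("PHEN:0000009", "PHEN:0000010") %in% link$unmapped))
  expect_false(any(link$mappings$subject_id %in% link$unmapped))
  expect_equal(link$summary$classes_under_root, 8L)
  expect_equal(link$summary$links, nrow(link$mappings))
  expect_lte(link$summary$classes_under_root, link$summary$n_phenotypes)
})

test_that("only the deepest trait superclass is emitted unless closure is requested", {
  link <- fx_link()
  # Hypolysinemia is also entailed under the amino-acid trait, but that
  # link is redundant given the lysine one
  hypo <- link$mappings[link$mappings$subject_id == "PHEN:0000001", ]
  expect_equal(hypo$object_id, TRAIT[["blood lysine amount"]])

  full <- link_phenotypes(fx_release(), fx_bundle()$mini_phenotype, closure = TRUE)
  hypo_full <- full$mappings[full$mappings$subject_id == "PHEN:0000001", ]
  expect_setequal(
    hypo_full$object_id,
    c(TRAIT[["blood lysine amount"]], TRAIT[["blood amino acid amount"]])
  )
  expect_gt(full$summary$links, link$summary$links)
})

test_that("every mapping re-verifies by entailment on the merged ontology", {
  link <- fx_link()
  for (i in seq_len(nrow(link$mappings))) {
    expect_true(entails(
      link$merged,
      c_named(link$mappings$subject_id[i]),
      c_named(link$mappings$object_id[i])
    ))
  }
})

test_that("link extraction is idempotent on the merged ontology", {
  link <- fx_link()
  again <- link_phenotypes(link$merged, fx_bundle()$mini_phenotype)
  expect_equal(again$mappings, link$mappings)
  expect_equal(again$summary, link$summary)
})

test_that("disjoint vocabularies produce a warning and an empty result", {
  isolated <- new_ontology() |>
    ont_add_term("EXT:1", "thing one") |>
    ont_add_term("EXT:2", "thing two") |>
    ont_add_axiom(ax_subclass("EXT:1", "EXT:2"))
  expect_warning(
    out <- link_phenotypes(fx_release(), isolated),
    "share no reference namespaces"
  )
  expect_equal(nrow(out$mappings), 0L)
  expect_setequal(out$unmapped, c("EXT:1", "EXT:2"))
})

test_that("manifestations collect the abnormality states of an attribute", {
  link <- fx_link()
  expect_setequal(
    manifestations(link$merged, TRAIT[["head size"]], link$result),
    c("PHEN:0000003", "PHEN:0000004", "PHEN:0000005")
  )
  # an attribute with no phenotype children
  expect_length(
    manifestations(link$merged, TRAIT[["trochanter size"]], link$result), 0L
  )
  expect_error(
    manifestations(link$merged, "OBA:404", link$result), "unknown attribute"
  )
  # monotone under adding a new abnormality subclass
  merged2 <- link$merged |>
    ont_add_term("PHEN:0000011", "Borderline head size") |>
    ont_add_axiom(ax_subclass("PHEN:0000011", "PHEN:0000005"))
  expect_setequal(
    manifestations(merged2, TRAIT[["head size"]]),
    c("PHEN:0000003", "PHEN:0000004", "PHEN:0000005", "PHEN:0000011")
  )
})

test_that("link results expose tidy and glance views", {
  link <- fx_link()
  expect_identical(tidy(link), link$mappings)
  g <- glance(link)
  expect_equal(g$links, 8L)
  expect_equal(g$n_unmapped, length(link$unmapped))
})
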