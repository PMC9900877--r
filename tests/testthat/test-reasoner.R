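test_that("classification is reflexive and includes top on axiom-free ontologies", {
  ont <- new_ontology() |> ont_add_term("X:A") |> ont_add_term("X:B")
  res <- classify(ont)
  expect_setequal(res$subsumers[["X:A"]], c("X:A", "owl:Thing"))
  expect_setequal(res$subsumers[["X:B"]], c("X:B", "owl:Thing"))
  expect_length(res$equiv, 0L)

  # empty ontology classifies to an empty result
  expect_length(classify(new_ontology())$classes, 0L)
})

test_that("chemical hierarchy propagates through compiled definitions", {
  rel <- fx_release()
  res <- fx_result()
  # lysine [= amino acid, hence the lysine-in-blood trait classifies
  # under the amino-acid-in-blood trait with no asserted link
  expect_true(
    TRAIT[["blood amino acid amount"]] %in% res$subsumers[[TRAIT[["blood lysine amount"]]]]
  )
  expect_false(
    TRAIT[["blood lysine amount"]] %in% res$subsumers[[TRAIT[["blood amino acid amount"]]]]
  )
  # direct parents are reasoner-derived
  expect_true(
    TRAIT[["blood amino acid amount"]] %in%
      res$direct_parents[[TRAIT[["blood lysine amount"]]]]
  )
})

test_that("abnormality states classify under their state-neutral traits", {
  b <- fx_bundle()
  merged <- ont_merge(fx_release(), b$mini_phenotype)
  res <- classify(merged)
  expect_true(TRAIT[["blood lysine amount"]] %in% res$subsumers[["PHEN:0000001"]])
  expect_true(TRAIT[["brain ventricle size"]] %in% res$subsumers[["PHEN:0000006"]])
  expect_false(TRAIT[["blood glucose amount"]] %in% res$subsumers[["PHEN:0000001"]])
})

test_that("role chains compose characteristic-of with part-of", {
  ont <- new_ontology() |>
    ont_add_term("X:C") |> ont_add_term("X:X") |> ont_add_term("X:Y") |>
    ont_add_role("r:co") |> ont_add_role("r:po") |> ont_add_role("r:copo") |>
    ont_add_axiom(
      ax_role_chain("r:co", "r:po", "r:copo"),
      ax_subclass("X:C", c_some("r:co", "X:X")),
      ax_subclass("X:X", c_some("r:po", "X:Y"))
    )
  expect_true(entails(ont, c_named("X:C"), c_some("r:copo", "X:Y")))
  expect_false(entails(ont, c_named("X:C"), c_some("r:po", "X:Y")))
})

test_that("entails answers arbitrary expression queries", {
  rel <- fx_release()
  expect_true(entails(rel, "CHEBI:25094", "owl:Thing"))
  expect_true(entails(
    rel,
    parse_class_expression(
      "PATO:0001997 and (RO:0000052 some (CHEBI:25094 and (BFO:0000050 some UBERON:0000178)))"
    ),
    c_named(TRAIT[["blood lysine amount"]])
  ))
  expect_false(entails(rel, "CHEBI:25094", "CHEBI:17234"))
})

test_that("DL queries retrieve named subclasses and exclude deprecated terms", {
  rel <- fx_release()
  q <- "PATO:0000051 and (RO:0002314 some UBERON:0004535)"
  expect_setequal(
    query_named_subclasses(rel, q),
    c(TRAIT[["heart morphology"]], TRAIT[["aorta morphology"]])
  )
  # owl:Thing retrieves every live class
  expect_setequal(query_named_subclasses(rel, "owl:Thing"), names(rel$terms))
  # deprecation removes a class from query results
  rel$terms[[TRAIT[["heart morphology"]]]]$deprecated <- TRUE
  expect_setequal(query_named_subclasses(rel, q), TRAIT[["aorta morphology"]])
  # empty ontology yields nothing
  expect_length(query_named_subclasses(new_ontology(), c_named("owl:Thing")), 0L)
})

test_that("saturation agrees with the brute-force oracle on seeded ontologies", {
  # a fast screen; the full 200-seed sweep runs in the acceptance suite
  for (s in 1:40) {
    ont <- random_el_ontology(
      s, n_classes = 5 + (s %% 18), n_roles = s %% 4, n_axioms = 8 + (s %% 40)
    )
    expect_identical(
      classify(ont)$subsumers, brute_force_subsumers(ont)$subsumers,
      info = paste("seed", s)
    )
  }
})

test_that("adding axioms never removes entailed subsumptions", {
  for (s in c(3, 11, 27, 42, 77)) {
    full <- random_el_ontology(s, n_classes = 12, n_roles = 2, n_axioms = 30)
    sub <- full
    sub$axioms <- full$axioms[1:18]
    res_sub <- classify(sub)$subsumers
    res_full <- classify(full)$subsumers
    for (C in names(res_sub)) {
      expect_true(all(res_sub[[C]] %in% res_full[[C]]),
                  info = paste("seed", s, "class", C))
    }
  }
})

test_that("saturation stays within the subexpression closure", {
  for (s in c(5, 19, 60)) {
    ont <- random_el_ontology(s, n_classes = 10, n_roles = 3, n_axioms = 40)
    nrm <- eqtraits:::normalize_ontology(ont)
    closure <- unique(unlist(lapply(ont$axioms, function(ax) {
      exprs <- switch(ax$type,
        subclass = list(ax$sub, ax$sup),
        equiv = list(ax$expr),
        list()
      )
      unlist(lapply(exprs, function(e) {
        vapply(eqtraits:::subexpressions(e), expr_key, character(1))
      }))
    })))
    n_complex <- sum(!closure %in% c(names(ont$terms), "owl:Thing"))
    expect_lte(length(nrm$atoms), length(ont$terms) + n_complex + 1L)
  }
})

test_that("equivalence groups and direct parents form a transitive reduction", {
  ont <- new_ontology() |>
    ont_add_term("X:A") |> ont_add_term("X:B") |> ont_add_term("X:C") |>
    ont_add_term("X:D") |>
    ont_add_axiom(
      ax_subclass("X:A", "X:B"), ax_subclass("X:B", "X:C"),
      ax_subclass("X:C", "X:B"), ax_subclass("X:C", "X:D")
    )
  res <- classify(ont)
  expect_equal(res$equiv, list(c("X:B", "X:C")))
  # A's only direct parent is the B/C group (represented by X:B); D is
  # reachable through it and must not appear as direct
  expect_equal(res$direct_parents[["X:A"]], "X:B")
  expect_equal(res$direct_parents[["X:B"]], "X:D")

  td <- tidy(res)
  expect_true(all(c("class", "subsumer") %in% names(td)))
  expect_true(nrow(glance(res)) == 1L)
})

test_that("classification rejects nothing within the fragment but is total", {
  # large-ish random input still terminates quickly
  ont <- random_el_ontology(99, n_classes = 25, n_roles = 3, n_axioms = 60)
  expect_s3_class(classify(ont), "eq_classification")
})
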