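test_that("label normalization lowercases, strips punctuation and stop words", {
  expect_equal(normalize_label("Lysine measurement"), "lysine")
  expect_equal(normalize_label("trait"), character(0))
  expect_equal(
    normalize_label("Blood glucose (fasting) Trait"),
    c("blood", "glucose", "fasting")
  )
  # idempotent on its own output
  for (lbl in c("Trochanter Size trait", "lysine measurement", "x-y z")) {
    once <- normalize_label(lbl)
    expect_equal(normalize_label(paste(once, collapse = " ")), once)
  }
})

test_that("exact matching hits labels and exact synonyms with no false positives", {
  cand <- match_terms(fixture_external_vocab(), fx_release())
  by_id <- function(id) cand[cand$external_id == id, ]

  expect_equal(by_id("EXT:0000001")$kind, "EXACT_LABEL")
  expect_equal(by_id("EXT:0000001")$matched_trait, TRAIT[["trochanter size"]])
  expect_equal(by_id("EXT:0000005")$matched_trait, TRAIT[["blood glucose amount"]])
  # synonym-mediated match: external exact synonym against the trait's
  # generated exact synonym
  expect_equal(by_id("EXT:0000007")$kind, "EXACT_SYNONYM")
  expect_equal(by_id("EXT:0000007")$matched_trait, TRAIT[["blood lysine amount"]])

  exact <- cand[cand$kind %in% c("EXACT_LABEL", "EXACT_SYNONYM"), ]
  expect_gte(nrow(exact), 7L)
  # zero false exact matches: every matched trait label normalizes to the
  # matching external form
  for (i in seq_len(nrow(exact))) {
    ext_t <- fixture_external_vocab()$terms[[exact$external_id[i]]]
    ext_forms <- c(list(ext_t$label), lapply(ext_t$synonyms, `[[`, "text"))
    ext_norm <- vapply(ext_forms, function(x) {
      paste(normalize_label(x), collapse = " ")
    }, character(1))
    trait_t <- fx_release()$terms[[exact$matched_trait[i]]]
    trait_forms <- c(list(trait_t$label), lapply(trait_t$synonyms, `[[`, "text"))
    trait_norm <- vapply(trait_forms, function(x) {
      paste(normalize_label(x), collapse = " ")
    }, character(1))
    expect_true(any(ext_norm %in% trait_norm), info = exact$external_id[i])
  }
})

test_that("ambiguous normalized targets yield NONE with a note", {
  traits <- fx_release() |>
    ont_add_term("OBA:9000010", "head size (duplicate)") |>
    ont_add_axiom(ax_equiv("OBA:9000010", c_and(
      c_named("PATO:0000117"), c_some("RO:0000052", "UBERON:0000033"),
      c_some("RO:0000052", "UBERON:0000970")
    )))
  traits$terms[["OBA:9000010"]]$label <- "Head  Size" # normalizes identically
  ext <- new_ontology() |> ont_add_term("EXT:1", "head size")
  cand <- match_terms(ext, traits)
  expect_equal(cand$kind, "NONE")
  expect_match(cand$note, "ambiguous")
  expect_match(cand$note, "OBA:1000001")
  expect_match(cand$note, "OBA:9000010")
})

test_that("decomposition scans reference ontologies in order and fills slots by range", {
  b <- fx_bundle()
  refs <- fx_matcher_refs()
  pats <- b$patterns[c("entity_attribute", "chemical_in_entity_attribute",
                       "role_attribute")]

  dec <- propose_decomposition("lysine measurement", refs, pats)
  expect_equal(dec$kind, "DECOMPOSITION")
  expect_equal(dec$pattern_id, "entity_attribute")
  expect_equal(
    eqtraits:::deserialize_bindings(dec$bindings),
    c(entity = "CHEBI:25094")
  )

  dec3 <- propose_decomposition("blood lysine amount", refs, pats)
  expect_equal(dec3$pattern_id, "chemical_in_entity_attribute")
  expect_equal(
    eqtraits:::deserialize_bindings(dec3$bindings),
    c(attribute = "PATO:0000070", chemical = "CHEBI:25094",
      location = "UBERON:0000178")
  )

  none <- propose_decomposition("xyzzy measurement", refs, pats)
  expect_equal(none$kind, "NONE")

  # multi-token reference labels are matched as contiguous runs
  dec4 <- propose_decomposition("forelimb skeleton size", refs, pats)
  expect_equal(
    eqtraits:::deserialize_bindings(dec4$bindings),
    c(attribute = "PATO:0000117", entity = "UBERON:0001440")
  )
})

test_that("candidate generation tries exact matching before decomposition", {
  cand <- generate_candidates(
    fixture_external_vocab(), fx_release(), fx_matcher_refs(),
    fx_bundle()$patterns[1:3]
  )
  expect_equal(nrow(cand), 10L)
  # no candidate is both exact and decomposed
  expect_false(any(
    cand$kind %in% c("EXACT_LABEL", "EXACT_SYNONYM") & !is.na(cand$bindings)
  ))
  # "lysine measurement" has an exact-matchable substring but no exact
  # trait target: it must fall through to decomposition
  lys <- cand[cand$external_label == "lysine measurement", ]
  expect_equal(lys$kind, "DECOMPOSITION")
  expect_setequal(
    cand$kind[cand$external_id %in% c("EXT:0000009", "EXT:0000010")], "NONE"
  )
})

test_that("review decisions split into SSSOM mappings and filler rows", {
  ext <- fixture_external_vocab()
  cand <- generate_candidates(ext, fx_release(), fx_matcher_refs(),
                              fx_bundle()$patterns[1:3])

  all_rejected <- tibble::tibble(
    external_id = cand$external_id, decision = "REJECTED"
  )
  out0 <- apply_review(cand, all_rejected, ext)
  expect_equal(nrow(out0$mappings), 0L)
  expect_equal(nrow(out0$fillers), 0L)

  review <- tibble::tibble(
    external_id = c("EXT:0000001", "EXT:0000008"),
    decision = "ACCEPTED"
  )
  out <- apply_review(cand, review, ext, minter = id_minter("OBA", 5000000L))
  expect_equal(out$mappings$subject_id, "EXT:0000001")
  expect_equal(out$mappings$object_id, TRAIT[["trochanter size"]])
  expect_equal(out$mappings$mapping_justification, "semapv:LexicalMatching")
  expect_equal(out$fillers$defined_class, "OBA:5000000")
  expect_equal(out$fillers$entity, "CHEBI:25094")

  expect_error(
    apply_review(cand, tibble::tibble(external_id = "EXT:404",
                                      decision = "ACCEPTED"), ext),
    "unknown candidate"
  )
})

test_that("an accepted decomposition compiles to a label matching the external term", {
  b <- fx_bundle()
  refs <- fx_refs()
  cand <- propose_decomposition("blood lysine amount", fx_matcher_refs(),
                                b$patterns[1:3])
  bindings <- eqtraits:::deserialize_bindings(cand$bindings)
  row <- c(list(defined_class = "OBA:5000000"), as.list(bindings))
  out <- compile_row(b$patterns$chemical_in_entity_attribute, row, refs)
  expect_equal(
    paste(normalize_label(out$term$label), collapse = " "),
    paste(normalize_label("blood lysine amount"), collapse = " ")
  )
})
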