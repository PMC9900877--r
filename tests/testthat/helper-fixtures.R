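# Shared fixture objects, computed once per test run.
fx_env <- new.env()

fx_bundle <- function() {
  if (is.null(fx_env$bundle)) fx_env$bundle <- build_fixture_bundle()
  fx_env$bundle
}

fx_refs <- function() {
  if (is.null(fx_env$refs)) fx_env$refs <- fixture_refs(fx_bundle())
  fx_env$refs
}

fx_release <- function() {
  if (is.null(fx_env$release)) fx_env$release <- fixture_release(fx_bundle())
  fx_env$release
}

fx_result <- function() {
  if (is.null(fx_env$result)) fx_env$result <- classify(fx_release())
  fx_env$result
}

fx_link <- function() {
  if (is.null(fx_env$link)) {
    fx_env$link <- link_phenotypes(fx_release(), fx_bundle()$mini_phenotype)
  }
  fx_env$link
}

fx_matcher_refs <- function() {
  b <- fx_bundle()
  list(b$mini_chemical, b$mini_anatomy, b$mini_characteristics)
}

# ids of the compiled trait fixtures, by label, for readable assertions
TRAIT <- c(
  "trochanter size" = "OBA:0002360",
  "head size" = "OBA:1000001",
  "eye size" = "OBA:1000002",
  "ulna size" = "OBA:1000003",
  "forelimb skeleton size" = "OBA:1000004",
  "brain ventricle size" = "OBA:0002294",
  "heart morphology" = "OBA:1000005",
  "aorta morphology" = "OBA:1000006",
  "head morphology" = "OBA:1000007",
  "blood lysine amount" = "OBA:2020005",
  "blood glucose amount" = "OBA:VT0000188",
  "blood amino acid amount" = "OBA:1000008",
  "serum metabolite amount" = "OBA:2050092"
)
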