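# Phenotype-to-trait integration: merge an EQ-axiomatised phenotype
# ontology with a trait release, classify, and read the entailed
# phenotype-under-trait subsumptions off the materialized hierarchy as
# SSSOM mappings. A phenotype ("Hypolysinemia": an abnormal decreased
# amount of lysine in blood) lands under the state-neutral trait ("blood
# lysine amount") because its state characteristic classifies under the
# trait's attribute and the bearers coincide.

#' Link phenotype classes to trait terms
#'
#' For each live phenotype class entailed under at least one compiled
#' trait term (a term carrying an equivalence axiom in `traits`), emits
#' one SSSOM row per non-redundant (deepest) trait superclass with
#' predicate `skos:broadMatch` and justification
#' `semapv:LogicalReasoning`. With `closure = TRUE` every entailed trait
#' superclass is emitted instead.
#'
#' @param traits Trait release ontology (compiled terms merged with
#'   their reference ontologies).
#' @param pheno Phenotype ontology sharing the reference vocabularies.
#' @param closure Emit the full superclass closure rather than only the
#'   deepest trait superclasses.
#' @return A list of class `eq_link_result`: `mappings` (SSSOM tibble),
#'   `summary` (tibble: `links`, `classes_under_root`, `n_phenotypes`),
#'   `unmapped` (character vector of phenotype ids with no link), and
#'   `merged`/`result` (the merged ontology and its classification, for
#'   reuse).
#' @export
link_phenotypes <- function(traits, pheno, closure = FALSE) {
  pheno_refs <- unique(curie_prefix(unlist(lapply(pheno$axioms, axiom_named_ids))))
  if (!length(intersect(pheno_refs, curie_prefix(names(traits$terms))))) {
    warning("phenotype and trait ontologies share no reference namespaces; ",
            "nothing can be linked", call. = FALSE)
    return(structure(
      list(
        mappings = empty_sssom(),
        summary = tibble::tibble(links = 0L, classes_under_root = 0L,
                                 n_phenotypes = length(pheno$terms)),
        unmapped = sort(names(pheno$terms)),
        merged = NULL, result = NULL
      ),
      class = "eq_link_result"
    ))
  }

  merged <- ont_merge(traits, pheno)
  result <- classify(merged)
  trait_ids <- setdiff(
    intersect(names(ont_equiv_map(traits)), ont_live_ids(traits)),
    names(pheno$terms)
  )
  pheno_ids <- sort(intersect(names(pheno$terms), ont_live_ids(merged)))
  subs <- result$subsumers

  rows <- list()
  mapped <- character()
  for (P in pheno_ids) {
    sups <- intersect(subs[[P]], trait_ids)
    if (!length(sups)) next
    mapped <- c(mapped, P)
    keep <- if (closure) sups else {
      Filter(function(A) {
        !any(vapply(sups, function(A2) {
          A2 != A && A %in% subs[[A2]] && !A2 %in% subs[[A]]
        }, logical(1)))
      }, sups)
    }
    for (A in sort(keep)) {
      rows[[length(rows) + 1L]] <- sssom_row(
        subject_id = P, subject_label = ont_label(merged, P),
        predicate_id = "skos:broadMatch",
        object_id = A, object_label = ont_label(merged, A),
        mapping_justification = "semapv:LogicalReasoning"
      )
    }
  }
  mappings <- if (length(rows)) dplyr::bind_rows(rows) else empty_sssom()
  structure(
    list(
      mappings = mappings,
      summary = tibble::tibble(
        links = nrow(mappings),
        classes_under_root = length(mapped),
        n_phenotypes = length(pheno_ids)
      ),
      unmapped = setdiff(pheno_ids, mapped),
      merged = merged,
      result = result
    ),
    class = "eq_link_result"
  )
}

#' @export
print.eq_link_result <- function(x, ...) {
  cat("<phenotype-trait links> ", x$summary$links, " mapping(s); ",
      x$summary$classes_under_root, "/", x$summary$n_phenotypes,
      " phenotype class(es) under a trait; ", length(x$unmapped),
      " unmapped\n", sep = "")
  invisible(x)
}

#' Mapping table of a link result
#' @param x An `eq_link_result`.
#' @param ... Unused.
#' @return The SSSOM mappings tibble.
#' @export
tidy.eq_link_result <- function(x, ...) x$mappings

#' One-row summary of a link result
#' @param x An `eq_link_result`.
#' @param ... Unused.
#' @return The summary tibble plus the unmapped count.
#' @export
glance.eq_link_result <- function(x, ...) {
  dplyr::mutate(x$summary, n_unmapped = length(x$unmapped))
}

#' Phenotype manifestations of a trait term
#'
#' All phenotype-namespace classes entailed under the given attribute in
#' a merged (trait + phenotype) ontology; e.g. a head-size trait collects
#' its decreased/increased/abnormal state classes.
#'
#' @param merged Merged ontology (e.g. `link_phenotypes()$merged`).
#' @param attribute Trait class id.
#' @param result Optional pre-computed classification of `merged`.
#' @param prefix Namespace prefix(es) of phenotype classes; defaults to
#'   every prefix other than the attribute's own.
#' @return Sorted character vector of phenotype class ids.
#' @export
manifestations <- function(merged, attribute, result = NULL, prefix = NULL) {
  if (!attribute %in% names(merged$terms)) {
    stop("unknown attribute id: ", attribute, call. = FALSE)
  }
  if (is.null(result)) result <- classify(merged)
  live <- ont_live_ids(merged)
  hits <- Filter(function(C) {
    C != attribute && attribute %in% result$subsumers[[C]]
  }, live)
  if (is.null(prefix)) {
    hits <- hits[curie_prefix(hits) != curie_prefix(attribute)]
  } else {
    hits <- hits[curie_prefix(hits) %in% prefix]
  }
  sort(hits)
}
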