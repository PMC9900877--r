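# Ontology container: term records, roles, axioms, prefix map. Kept as a
# plain S3 list (ape/igraph style); tabular views are available via
# ont_terms()/ont_axioms() which return tibbles.

#' Create an empty ontology
#'
#' @param prefixes Named character vector, prefix -> URI base.
#' @return An `eq_ontology`.
#' @export
new_ontology <- function(prefixes = default_prefixes()) {
  structure(
    list(
      terms = list(),    # id -> term record
      roles = list(),    # id -> label
      axioms = list(),   # list of eq_axiom
      prefixes = prefixes
    ),
    class = "eq_ontology"
  )
}

new_term <- function(id, label = NA_character_, definition = NA_character_,
                     synonyms = list(), deprecated = FALSE,
                     replaced_by = NA_character_, subsets = character()) {
  list(
    id = id, label = label, definition = definition, synonyms = synonyms,
    deprecated = isTRUE(deprecated), replaced_by = replaced_by,
    subsets = subsets
  )
}

#' Add or update a class term
#'
#' @param ont An `eq_ontology`.
#' @param id Class id string.
#' @param label,definition Optional annotation text.
#' @param synonyms List of `list(text=, scope=)`; scope one of EXACT,
#'   BROAD, NARROW, RELATED.
#' @param deprecated Obsoletion flag. By convention a deprecated term's
#'   label starts with `"obsolete "` and carries no logical axioms
#'   (enforced by the QC module, not here).
#' @param replaced_by Optional id of the replacement term.
#' @param subsets Character vector of subset tags (e.g. `attribute_slim`
#'   marking attribute-level characteristics).
#' @return The modified ontology.
#' @export
ont_add_term <- function(ont, id, label = NA_character_,
                         definition = NA_character_, synonyms = list(),
                         deprecated = FALSE, replaced_by = NA_character_,
                         subsets = character()) {
  stopifnot(inherits(ont, "eq_ontology"))
  ont$terms[[id]] <- new_term(id, label, definition, synonyms, deprecated,
                              replaced_by, subsets)
  ont
}

#' Add or update an object property (role)
#' @param ont An `eq_ontology`.
#' @param id Role id string.
#' @param label Role label.
#' @return The modified ontology.
#' @export
ont_add_role <- function(ont, id, label = NA_character_) {
  stopifnot(inherits(ont, "eq_ontology"))
  ont$roles[[id]] <- label
  ont
}

#' Add axioms to an ontology
#' @param ont An `eq_ontology`.
#' @param ... `eq_axiom` objects (or a single list of them).
#' @return The modified ontology.
#' @export
ont_add_axiom <- function(ont, ...) {
  axs <- list(...)
  if (length(axs) == 1L && is.list(axs[[1]]) && !inherits(axs[[1]], "eq_axiom")) {
    axs <- axs[[1]]
  }
  for (ax in axs) {
    stopifnot(inherits(ax, "eq_axiom"))
    if (ax$type == "equiv") {
      prev <- vapply(ont$axioms, function(a) a$type == "equiv" && a$id == ax$id, logical(1))
      if (any(prev)) {
        stop("ontology already holds an equivalence axiom for ", ax$id, call. = FALSE)
      }
    }
    ont$axioms[[length(ont$axioms) + 1L]] <- ax
  }
  ont
}

#' Term table of an ontology
#' @param ont An `eq_ontology`.
#' @return A tibble with one row per class term.
#' @export
ont_terms <- function(ont) {
  stopifnot(inherits(ont, "eq_ontology"))
  if (!length(ont$terms)) {
    return(tibble::tibble(
      id = character(), label = character(), definition = character(),
      deprecated = logical(), replaced_by = character(), n_synonyms = integer()
    ))
  }
  purrr::map_dfr(ont$terms, function(t) {
    tibble::tibble(
      id = t$id, label = t$label, definition = t$definition,
      deprecated = t$deprecated, replaced_by = t$replaced_by,
      n_synonyms = length(t$synonyms)
    )
  }) |> dplyr::arrange(.data$id)
}

#' Axiom table of an ontology
#' @param ont An `eq_ontology`.
#' @return A tibble with columns `type` and `axiom` (canonical rendering).
#' @export
ont_axioms <- function(ont) {
  stopifnot(inherits(ont, "eq_ontology"))
  tibble::tibble(
    type = vapply(ont$axioms, function(a) a$type, character(1)),
    axiom = vapply(ont$axioms, axiom_key, character(1))
  )
}

ont_live_ids <- function(ont) {
  ids <- names(ont$terms)
  dep <- vapply(ont$terms, function(t) t$deprecated, logical(1))
  ids[!dep]
}

# id -> label lookup (named character)
ont_labels <- function(ont) {
  if (!length(ont$terms)) return(stats::setNames(character(), character()))
  vapply(ont$terms, function(t) t$label %||% NA_character_, character(1))
}

ont_label <- function(ont, id) {
  t <- ont$terms[[id]]
  if (is.null(t) || is.na(t$label)) id else t$label
}

# named-class equivalence axioms keyed by defined class id
ont_equiv_map <- function(ont) {
  eq <- Filter(function(a) a$type == "equiv", ont$axioms)
  stats::setNames(lapply(eq, function(a) a$expr), vapply(eq, function(a) a$id, character(1)))
}

#' Merge ontologies
#'
#' Union of terms, roles, axioms and prefixes. Later arguments win on term
#' metadata clashes; duplicate axioms (by canonical key) are dropped.
#'
#' @param ... `eq_ontology` objects.
#' @return The merged `eq_ontology`.
#' @export
ont_merge <- function(...) {
  onts <- list(...)
  if (length(onts) == 1L && !inherits(onts[[1]], "eq_ontology")) onts <- onts[[1]]
  out <- new_ontology(prefixes = onts[[1]]$prefixes)
  seen <- character()
  for (o in onts) {
    stopifnot(inherits(o, "eq_ontology"))
    out$prefixes <- c(out$prefixes[setdiff(names(out$prefixes), names(o$prefixes))], o$prefixes)
    for (id in names(o$terms)) out$terms[[id]] <- o$terms[[id]]
    for (id in names(o$roles)) out$roles[[id]] <- o$roles[[id]]
    for (ax in o$axioms) {
      k <- axiom_key(ax)
      if (!k %in% seen) {
        seen <- c(seen, k)
        out$axioms[[length(out$axioms) + 1L]] <- ax
      }
    }
  }
  out
}

# ids referenced by axioms but not declared; list(classes=, roles=)
ont_dangling <- function(ont) {
  cls <- unique(unlist(lapply(ont$axioms, axiom_named_ids)))
  rls <- unique(unlist(lapply(ont$axioms, axiom_role_ids)))
  list(
    classes = setdiff(setdiff(cls, names(ont$terms)), TOP),
    roles = setdiff(rls, names(ont$roles))
  )
}

#' Validate ontology referential integrity
#'
#' Checks that every class and role id referenced by an axiom is declared.
#'
#' @param ont An `eq_ontology`.
#' @param error Raise an error on failure (default) or return the dangling
#'   id list invisibly.
#' @return `ont`, invisibly, if valid.
#' @export
ont_validate <- function(ont, error = TRUE) {
  d <- ont_dangling(ont)
  if (length(d$classes) || length(d$roles)) {
    msg <- paste0(
      "undeclared identifiers in axioms: ",
      paste(c(d$classes, d$roles), collapse = ", ")
    )
    if (error) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  invisible(ont)
}

#' @export
print.eq_ontology <- function(x, ...) {
  cat("<ontology> ", length(x$terms), " classes, ", length(x$roles),
      " roles, ", length(x$axioms), " axioms\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
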