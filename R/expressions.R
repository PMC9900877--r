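# EL class-expression data model: named classes, conjunctions, existential
# restrictions. This is the only expression language the toolkit supports;
# parsers reject anything outside it (unions, negation, universal
# restrictions) so every downstream component can rely on the EL profile.

TOP <- "owl:Thing"

#' Named class expression
#' @param id Class id as a `"PREFIX:local"` string.
#' @return An `eq_expr` of variant `named`.
#' @export
c_named <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  structure(list(type = "named", id = id), class = "eq_expr")
}

#' Conjunction (ObjectIntersectionOf)
#' @param ... Operand expressions (or a single list of them).
#' @return An `eq_expr` of variant `and` (canonicalized).
#' @export
c_and <- function(...) {
  ops <- list(...)
  if (length(ops) == 1L && is.list(ops[[1]]) && !inherits(ops[[1]], "eq_expr")) {
    ops <- ops[[1]]
  }
  stopifnot(length(ops) >= 1L)
  canonicalize(structure(list(type = "and", ops = ops), class = "eq_expr"))
}

#' Existential restriction (ObjectSomeValuesFrom)
#' @param role Object property id string.
#' @param filler Filler expression (or class id string).
#' @return An `eq_expr` of variant `some`.
#' @export
c_some <- function(role, filler) {
  if (is.character(filler)) filler <- c_named(filler)
  structure(list(type = "some", role = role, filler = filler), class = "eq_expr")
}

#' Canonicalize a class expression
#'
#' Flattens nested conjunctions, deduplicates and sorts operands by a total
#' order (lexicographic on the rendered canonical key), and collapses
#' single-operand conjunctions. Idempotent, and a congruence for
#' entailment: two expressions with the same canonical form are logically
#' equivalent.
#'
#' @param expr An `eq_expr`.
#' @return The canonical `eq_expr`.
#' @export
canonicalize <- function(expr) {
  stopifnot(inherits(expr, "eq_expr"))
  switch(expr$type,
    named = expr,
    some = structure(
      list(type = "some", role = expr$role, filler = canonicalize(expr$filler)),
      class = "eq_expr"
    ),
    and = {
      flat <- list()
      for (op in expr$ops) {
        op <- canonicalize(if (is.character(op)) c_named(op) else op)
        if (op$type == "and") flat <- c(flat, op$ops) else flat <- c(flat, list(op))
      }
      keys <- vapply(flat, expr_key, character(1))
      keep <- !duplicated(keys)
      flat <- flat[keep][order(keys[keep])]
      if (length(flat) == 1L) {
        flat[[1]]
      } else {
        structure(list(type = "and", ops = flat), class = "eq_expr")
      }
    },
    stop("unknown expression variant: ", expr$type)
  )
}

#' Canonical string key of an expression
#'
#' Deterministic rendering of the canonical form; equal keys imply logical
#' equivalence. Used for expression identity in the reasoner, uniqueness
#' QC and serialization ordering.
#'
#' @param expr An `eq_expr` (canonicalized internally).
#' @return A single string.
#' @export
expr_key <- function(expr) {
  if (is.character(expr)) return(expr)
  switch(expr$type,
    named = expr$id,
    some = paste0("(", expr$role, " some ", expr_key(expr$filler), ")"),
    and = {
      keys <- sort(unique(vapply(expr$ops, expr_key, character(1))))
      if (length(keys) == 1L) keys else paste0("(", paste(keys, collapse = " and "), ")")
    }
  )
}

expr_is_named <- function(e) inherits(e, "eq_expr") && e$type == "named"

# All distinct subexpressions (canonical), including expr itself.
subexpressions <- function(expr) {
  expr <- canonicalize(expr)
  out <- list(expr)
  if (expr$type == "and") {
    for (op in expr$ops) out <- c(out, subexpressions(op))
  } else if (expr$type == "some") {
    out <- c(out, subexpressions(expr$filler))
  }
  keys <- vapply(out, expr_key, character(1))
  out[!duplicated(keys)]
}

# Named class ids mentioned anywhere in an expression.
expr_named_ids <- function(expr) {
  switch(expr$type,
    named = expr$id,
    some = expr_named_ids(expr$filler),
    and = unique(unlist(lapply(expr$ops, expr_named_ids)))
  )
}

# Role ids mentioned anywhere in an expression.
expr_role_ids <- function(expr) {
  switch(expr$type,
    named = character(),
    some = unique(c(expr$role, expr_role_ids(expr$filler))),
    and = unique(unlist(lapply(expr$ops, expr_role_ids)))
  )
}

#' @export
print.eq_expr <- function(x, ...) {
  cat("<class expression> ", expr_key(x), "\n", sep = "")
  invisible(x)
}

## ---- axioms -----------------------------------------------------------

#' Subclass axiom (GCIs permitted)
#' @param sub,sup Class expressions or id strings. A complex `sub` makes
#'   this a General Concept Inclusion.
#' @return An `eq_axiom`.
#' @export
ax_subclass <- function(sub, sup) {
  if (is.character(sub)) sub <- c_named(sub)
  if (is.character(sup)) sup <- c_named(sup)
  structure(
    list(type = "subclass", sub = canonicalize(sub), sup = canonicalize(sup)),
    class = "eq_axiom"
  )
}

#' Equivalent-classes axiom (named class == expression)
#' @param id Named class id string (always the left-hand side).
#' @param expr Defining class expression.
#' @return An `eq_axiom`.
#' @export
ax_equiv <- function(id, expr) {
  stopifnot(is.character(id), length(id) == 1L)
  if (is.character(expr)) expr <- c_named(expr)
  structure(
    list(type = "equiv", id = id, expr = canonicalize(expr)),
    class = "eq_axiom"
  )
}

#' Role (object property) hierarchy axiom
#' @param sub,sup Role id strings.
#' @return An `eq_axiom`.
#' @export
ax_role_sub <- function(sub, sup) {
  structure(list(type = "role_sub", sub = sub, sup = sup), class = "eq_axiom")
}

#' Role chain axiom (first o second -> sup); length exactly 2
#' @param first,second,sup Role id strings.
#' @return An `eq_axiom`.
#' @export
ax_role_chain <- function(first, second, sup) {
  structure(
    list(type = "role_chain", first = first, second = second, sup = sup),
    class = "eq_axiom"
  )
}

axiom_key <- function(ax) {
  switch(ax$type,
    subclass = paste0("SubClassOf(", expr_key(ax$sub), " ", expr_key(ax$sup), ")"),
    equiv = paste0("EquivalentClasses(", ax$id, " ", expr_key(ax$expr), ")"),
    role_sub = paste0("SubObjectPropertyOf(", ax$sub, " ", ax$sup, ")"),
    role_chain = paste0(
      "SubObjectPropertyOf(ObjectPropertyChain(", ax$first, " ", ax$second, ") ",
      ax$sup, ")"
    )
  )
}

#' @export
print.eq_axiom <- function(x, ...) {
  cat("<axiom> ", axiom_key(x), "\n", sep = "")
  invisible(x)
}

axiom_named_ids <- function(ax) {
  switch(ax$type,
    subclass = unique(c(expr_named_ids(ax$sub), expr_named_ids(ax$sup))),
    equiv = unique(c(ax$id, expr_named_ids(ax$expr))),
    character()
  )
}

axiom_role_ids <- function(ax) {
  switch(ax$type,
    subclass = unique(c(expr_role_ids(ax$sub), expr_role_ids(ax$sup))),
    equiv = expr_role_ids(ax$expr),
    role_sub = c(ax$sub, ax$sup),
    role_chain = c(ax$first, ax$second, ax$sup)
  )
}
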