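# Consequence-based saturation reasoner for the supported EL fragment:
# conjunction, existential restriction, GCIs, equivalences, role hierarchy
# and role chains (length 2). Sound and complete for named-class
# subsumption over this fragment.
#
# Strategy: structural normalization to primitive axiom forms over atoms
# (named classes plus one fresh atom per distinct complex subexpression,
# defined equivalent to it — a conservative extension), then worklist
# completion with the classic EL rules:
#   conj:    A1 n ... n An [= B      (n >= 1, all Ai atomic)
#   ex_rhs:  A [= some r. B
#   ex_lhs:  some r. A [= B
# plus role hierarchy closure and chain composition. Derived facts:
#   S(A): atomic subsumers of A;  R(r): derived role edges (A,B).
# Everything is driven by a sorted-insertion worklist so traces are
# deterministic.

fresh_atom_prefix <- "_:x"

normalize_ontology <- function(ont) {
  stopifnot(inherits(ont, "eq_ontology"))
  st <- new.env(parent = emptyenv())
  st$atom_of <- new.env(parent = emptyenv())  # expr key -> atom
  st$n_fresh <- 0L
  st$conj <- list()     # list(lhs = chr, rhs = chr)
  st$ex_rhs <- list()   # list(lhs = chr, role = chr, filler = chr)
  st$ex_lhs <- list()   # list(role = chr, filler = chr, rhs = chr)
  st$extra_atoms <- character()

  atom_of <- function(expr) {
    expr <- canonicalize(expr)
    if (expr$type == "named") return(expr$id)
    key <- expr_key(expr)
    hit <- st$atom_of[[key]]
    if (!is.null(hit)) return(hit)
    st$n_fresh <- st$n_fresh + 1L
    x <- sprintf("%s%04d", fresh_atom_prefix, st$n_fresh)
    assign(key, x, envir = st$atom_of)
    st$extra_atoms <- c(st$extra_atoms, x)
    if (expr$type == "and") {
      ops <- vapply(expr$ops, atom_of, character(1))
      st$conj[[length(st$conj) + 1L]] <- list(lhs = ops, rhs = x)       # expr [= x
      for (o in ops) {                                                   # x [= expr
        st$conj[[length(st$conj) + 1L]] <- list(lhs = x, rhs = o)
      }
    } else { # some
      f <- atom_of(expr$filler)
      st$ex_lhs[[length(st$ex_lhs) + 1L]] <-
        list(role = expr$role, filler = f, rhs = x)                      # expr [= x
      st$ex_rhs[[length(st$ex_rhs) + 1L]] <-
        list(lhs = x, role = expr$role, filler = f)                      # x [= expr
    }
    x
  }

  role_subs <- list()
  chains <- list()
  for (ax in ont$axioms) {
    switch(ax$type,
      subclass = {
        st$conj[[length(st$conj) + 1L]] <-
          list(lhs = atom_of(ax$sub), rhs = atom_of(ax$sup))
      },
      equiv = {
        x <- atom_of(ax$expr)
        st$conj[[length(st$conj) + 1L]] <- list(lhs = ax$id, rhs = x)
        st$conj[[length(st$conj) + 1L]] <- list(lhs = x, rhs = ax$id)
      },
      role_sub = {
        role_subs[[length(role_subs) + 1L]] <- c(ax$sub, ax$sup)
      },
      role_chain = {
        chains[[length(chains) + 1L]] <-
          list(first = ax$first, second = ax$second, sup = ax$sup)
      },
      stop("unsupported axiom variant: ", ax$type, call. = FALSE)
    )
  }

  roles <- unique(c(
    names(ont$roles),
    unlist(lapply(ont$axioms, axiom_role_ids), use.names = FALSE)
  ))
  # reflexive-transitive closure of the role hierarchy
  superroles <- stats::setNames(as.list(roles), roles)
  repeat {
    changed <- FALSE
    for (rs in role_subs) {
      for (r in roles) {
        if (rs[1] %in% superroles[[r]] && !rs[2] %in% superroles[[r]]) {
          superroles[[r]] <- c(superroles[[r]], rs[2])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  named <- names(ont$terms)
  atoms <- unique(c(named, st$extra_atoms, TOP))
  list(
    atoms = atoms, named = named, roles = roles,
    conj = st$conj, ex_rhs = st$ex_rhs, ex_lhs = st$ex_lhs,
    superroles = superroles, chains = chains,
    atom_of = st$atom_of
  )
}

saturate <- function(nrm) {
  atoms <- nrm$atoms
  S <- new.env(parent = emptyenv())
  for (a in atoms) S[[a]] <- new.env(parent = emptyenv())
  Rout <- new.env(parent = emptyenv())
  Rin <- new.env(parent = emptyenv())
  for (r in nrm$roles) {
    Rout[[r]] <- new.env(parent = emptyenv())
    Rin[[r]] <- new.env(parent = emptyenv())
  }

  # indexes
  conj_by_elem <- new.env(parent = emptyenv())
  for (i in seq_along(nrm$conj)) {
    for (e in nrm$conj[[i]]$lhs) {
      conj_by_elem[[e]] <- c(conj_by_elem[[e]], i)
    }
  }
  exr_by_lhs <- new.env(parent = emptyenv())
  for (i in seq_along(nrm$ex_rhs)) {
    e <- nrm$ex_rhs[[i]]$lhs
    exr_by_lhs[[e]] <- c(exr_by_lhs[[e]], i)
  }
  # role -> filler -> chr vector of rhs
  exl <- new.env(parent = emptyenv())
  exl_roles_by_filler <- new.env(parent = emptyenv())
  for (ax in nrm$ex_lhs) {
    if (is.null(exl[[ax$role]])) exl[[ax$role]] <- new.env(parent = emptyenv())
    exl[[ax$role]][[ax$filler]] <- c(exl[[ax$role]][[ax$filler]], ax$rhs)
    exl_roles_by_filler[[ax$filler]] <-
      unique(c(exl_roles_by_filler[[ax$filler]], ax$role))
  }
  chains_by_first <- new.env(parent = emptyenv())
  chains_by_second <- new.env(parent = emptyenv())
  for (ch in nrm$chains) {
    chains_by_first[[ch$first]] <- c(chains_by_first[[ch$first]], list(ch))
    chains_by_second[[ch$second]] <- c(chains_by_second[[ch$second]], list(ch))
  }

  work <- vector("list", 4096L)
  w_head <- 0L; w_tail <- 0L
  push <- function(item) {
    w_tail <<- w_tail + 1L
    if (w_tail > length(work)) length(work) <<- 2L * w_tail
    work[[w_tail]] <<- item
  }
  push_sub <- function(A, B) {
    if (is.null(S[[A]][[B]])) push(list(k = "s", A = A, B = B))
  }
  push_edge <- function(A, r, B) push(list(k = "e", A = A, r = r, B = B))

  for (a in sort(atoms)) {
    push_sub(a, a)
    if (a != TOP) push_sub(a, TOP)
  }

  while (w_head < w_tail) {
    w_head <- w_head + 1L
    it <- work[[w_head]]
    if (it$k == "s") {
      A <- it$A; B <- it$B
      if (!is.null(S[[A]][[B]])) next
      assign(B, TRUE, envir = S[[A]])
      # conjunction rule
      for (i in conj_by_elem[[B]]) {
        ax <- nrm$conj[[i]]
        ok <- TRUE
        for (e in ax$lhs) if (is.null(S[[A]][[e]])) { ok <- FALSE; break }
        if (ok) push_sub(A, ax$rhs)
      }
      # existential introduction
      for (i in exr_by_lhs[[B]]) {
        ax <- nrm$ex_rhs[[i]]
        push_edge(A, ax$role, ax$filler)
      }
      # existential propagation: B entered S(A); A may be a role successor
      for (r in exl_roles_by_filler[[B]]) {
        rhs <- exl[[r]][[B]]
        preds <- Rin[[r]][[A]]
        if (!is.null(preds)) {
          for (X in ls(preds)) for (D in rhs) push_sub(X, D)
        }
      }
    } else {
      A <- it$A; B <- it$B
      for (r in nrm$superroles[[it$r]]) {
        out <- Rout[[r]][[A]]
        if (is.null(out)) { out <- new.env(parent = emptyenv()); Rout[[r]][[A]] <- out }
        if (!is.null(out[[B]])) next
        assign(B, TRUE, envir = out)
        inn <- Rin[[r]][[B]]
        if (is.null(inn)) { inn <- new.env(parent = emptyenv()); Rin[[r]][[B]] <- inn }
        assign(A, TRUE, envir = inn)
        # existential propagation over the new edge
        ex <- exl[[r]]
        if (!is.null(ex)) {
          for (f in ls(ex)) {
            if (!is.null(S[[B]][[f]])) for (D in ex[[f]]) push_sub(A, D)
          }
        }
        # chain composition
        for (ch in chains_by_first[[r]]) {
          succ <- Rout[[ch$second]][[B]]
          if (!is.null(succ)) for (C in ls(succ)) push_edge(A, ch$sup, C)
        }
        for (ch in chains_by_second[[r]]) {
          preds <- Rin[[ch$first]][[A]]
          if (!is.null(preds)) for (X in ls(preds)) push_edge(X, ch$sup, B)
        }
      }
    }
  }
  list(S = S, Rout = Rout, Rin = Rin)
}

#' Classify an ontology
#'
#' Computes the complete named-class subsumption preorder of an EL
#' ontology by rule saturation, together with its equivalence partition
#' and the transitive reduction (direct parents) of the induced partial
#' order.
#'
#' @param ont An `eq_ontology` within the supported fragment.
#' @return An `eq_classification` with fields `classes`, `subsumers`
#'   (named class -> character vector of named subsumers, always
#'   containing the class itself and `owl:Thing`), `equiv` (list of
#'   equivalence groups with more than one member), and `direct_parents`
#'   (named class -> character vector of direct named parents, using the
#'   lexicographically first member of each equivalence group as its
#'   representative).
#' @export
#' @examples
#' ont <- new_ontology() |>
#'   ont_add_term("CHEBI:25094", "lysine") |>
#'   ont_add_term("CHEBI:33709", "amino acid") |>
#'   ont_add_axiom(ax_subclass("CHEBI:25094", "CHEBI:33709"))
#' classify(ont)$subsumers[["CHEBI:25094"]]
classify <- function(ont) {
  nrm <- normalize_ontology(ont)
  sat <- saturate(nrm)
  named <- nrm$named
  keep <- c(named, TOP)
  subs <- lapply(stats::setNames(named, named), function(C) {
    sort(intersect(ls(sat$S[[C]]), keep))
  })

  # equivalence partition (groups of mutually subsuming classes)
  rep_of <- stats::setNames(named, named)
  groups <- list()
  if (length(named)) {
    seen <- character()
    for (C in sort(named)) {
      if (C %in% seen) next
      eqs <- sort(Filter(function(D) D != C && C %in% subs[[D]],
                         intersect(subs[[C]], named)))
      grp <- c(C, eqs)
      seen <- c(seen, grp)
      rep_of[grp] <- C
      if (length(grp) > 1L) groups[[length(groups) + 1L]] <- grp
    }
  }

  # direct parents: transitive reduction on equivalence representatives
  direct <- lapply(stats::setNames(named, named), function(C) {
    r <- rep_of[[C]]
    parents <- setdiff(unique(rep_of[intersect(subs[[C]], named)]), r)
    keep_p <- vapply(parents, function(p) {
      !any(vapply(parents, function(q) q != p && p %in% subs[[q]], logical(1)))
    }, logical(1))
    sort(unname(parents[keep_p]))
  })

  structure(
    list(
      classes = named,
      subsumers = subs,
      equiv = groups,
      representatives = rep_of,
      direct_parents = direct,
      state = list(nrm = nrm, sat = sat)
    ),
    class = "eq_classification"
  )
}

#' @export
print.eq_classification <- function(x, ...) {
  n_sub <- sum(lengths(x$subsumers))
  cat("<classification> ", length(x$classes), " classes, ", n_sub,
      " subsumptions, ", length(x$equiv), " equivalence group(s)\n", sep = "")
  invisible(x)
}

#' Subsumption table of a classification
#'
#' @param x An `eq_classification`.
#' @param ... Unused.
#' @return A tibble with columns `class`, `subsumer` (one row per entailed
#'   named subsumption, excluding reflexive rows and `owl:Thing`).
#' @export
tidy.eq_classification <- function(x, ...) {
  purrr::map_dfr(x$classes, function(C) {
    sups <- setdiff(x$subsumers[[C]], c(C, TOP))
    if (!length(sups)) return(NULL)
    tibble::tibble(class = C, subsumer = sups)
  })
}

#' One-row summary of a classification
#' @param x An `eq_classification`.
#' @param ... Unused.
#' @return A tibble with class/subsumption/equivalence counts.
#' @export
glance.eq_classification <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_subsumptions = nrow(tidy(x)),
    n_equiv_groups = length(x$equiv),
    mean_direct_parents = if (length(x$classes)) {
      mean(lengths(x$direct_parents))
    } else NA_real_
  )
}

# internal: does the saturated state entail named-atom subsumption a [= b
state_has_sub <- function(result, a, b) {
  !is.null(result$state$sat$S[[a]]) && !is.null(result$state$sat$S[[a]][[b]])
}

#' Test entailment of a subsumption between class expressions
#'
#' Introduces fresh query classes equivalent to `sub` and `sup`,
#' classifies, and reads off the result.
#'
#' @param ont An `eq_ontology`.
#' @param sub,sup Class expressions (`eq_expr`) or class id strings.
#' @return `TRUE` iff the ontology entails `sub` is a subclass of `sup`.
#' @export
entails <- function(ont, sub, sup) {
  if (is.character(sub)) sub <- c_named(sub)
  if (is.character(sup)) sup <- c_named(sup)
  if (expr_key(canonicalize(sub)) == expr_key(canonicalize(sup))) return(TRUE)
  if (expr_is_named(sup) && sup$id == TOP) return(TRUE)
  q1 <- "_:querySub"; q2 <- "_:querySup"
  ont$terms[[q1]] <- new_term(q1)
  ont$terms[[q2]] <- new_term(q2)
  ont <- ont_add_axiom(ont, ax_equiv(q1, sub), ax_equiv(q2, sup))
  res <- classify(ont)
  q2 %in% res$subsumers[[q1]]
}

#' Retrieve named subclasses of a query expression (DL query)
#'
#' @param ont An `eq_ontology`.
#' @param query A class expression (`eq_expr`), a class id string, or a
#'   Manchester-like query string (see [parse_class_expression()]).
#' @param include_deprecated Include obsoleted classes (default `FALSE`).
#' @param direct_only Unused placeholder for future use.
#' @return Sorted character vector of named classes entailed to be
#'   subclasses of the query (including any named class equivalent to it).
#' @export
#' @examples
#' # all classes: query owl:Thing
query_named_subclasses <- function(ont, query, include_deprecated = FALSE,
                                   direct_only = FALSE) {
  if (is.character(query)) {
    query <- if (query %in% c(names(ont$terms), TOP)) {
      c_named(query)
    } else {
      parse_class_expression(query)
    }
  }
  q <- "_:query"
  ont$terms[[q]] <- new_term(q)
  ont <- ont_add_axiom(ont, ax_equiv(q, query))
  res <- classify(ont)
  hits <- Filter(function(C) C != q && q %in% res$subsumers[[C]], res$classes)
  if (!include_deprecated) {
    dep <- vapply(hits, function(C) isTRUE(ont$terms[[C]]$deprecated), logical(1))
    hits <- hits[!dep]
  }
  sort(hits)
}
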