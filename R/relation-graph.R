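# Relation-graph materialization: convert a classified ontology into
# entailed named-class-to-named-class edges. Role edges come straight out
# of the saturation's derived role relations (an edge subject -r-> object
# exists iff the ontology entails subject [= some r. object); is_a edges
# are the transitive reduction of the taxonomy. Each role edge is flagged
# redundant when it is implied by another edge plus the class hierarchy.

#' Materialize entailed relation edges
#'
#' @param ont The classified `eq_ontology`.
#' @param result Its [classify()] result.
#' @param roles Character vector of role ids to materialize (each must be
#'   declared in `ont`); the empty default yields is_a edges only.
#' @param include_reflexive Emit `(C, r, C)` edges (default `FALSE`:
#'   suppressed as noise).
#' @param include_deprecated Include obsoleted classes (default `FALSE`).
#' @return Tibble with columns `subject`, `predicate`, `object`,
#'   `redundant`. `is_a` rows are already non-redundant.
#' @export
materialize <- function(ont, result, roles = character(),
                        include_reflexive = FALSE,
                        include_deprecated = FALSE) {
  stopifnot(inherits(result, "eq_classification"))
  undeclared <- setdiff(roles, names(ont$roles))
  if (length(undeclared)) {
    stop("role(s) not declared in the ontology: ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  }
  live <- if (include_deprecated) names(ont$terms) else ont_live_ids(ont)
  subs <- result$subsumers
  strictly_below <- function(a, b) {
    # a strictly below b (a [= b and not b [= a)
    b %in% subs[[a]] && !a %in% subs[[b]]
  }

  sat <- result$state$sat
  rows <- list()
  # role edges
  targets <- list()
  for (r in roles) {
    tr <- list()
    for (C in live) {
      routs <- sat$Rout[[r]]
      succ <- if (is.null(routs)) NULL else routs[[C]]
      if (is.null(succ)) next
      Ds <- character()
      for (X in ls(succ)) {
        Ds <- c(Ds, intersect(ls(sat$S[[X]]), live))
      }
      Ds <- sort(unique(Ds))
      if (!include_reflexive) Ds <- setdiff(Ds, C)
      if (length(Ds)) tr[[C]] <- Ds
    }
    targets[[r]] <- tr
  }
  for (r in roles) {
    tr <- targets[[r]]
    for (C in names(tr)) {
      for (D in tr[[C]]) {
        redundant <- any(vapply(setdiff(tr[[C]], D), function(D2) {
          strictly_below(D2, D)
        }, logical(1)))
        if (!redundant) {
          ups <- setdiff(intersect(subs[[C]], live), C)
          redundant <- any(vapply(ups, function(C2) {
            strictly_below(C, C2) && D %in% (tr[[C2]] %||% character())
          }, logical(1)))
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = C, predicate = r, object = D, redundant = redundant
        )
      }
    }
  }
  # is_a edges: transitive reduction (direct parents), live classes only
  for (C in live) {
    for (P in intersect(result$direct_parents[[C]], live)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = C, predicate = "is_a", object = P, redundant = FALSE
      )
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(subject = character(), predicate = character(),
                   object = character(), redundant = logical())
  }
  out[do.call(order, out[c("predicate", "subject", "object")]), ]
}

#' Non-redundant subset of materialized edges
#'
#' Drops every role edge implied by another edge plus the hierarchy
#' (object replaceable by a strictly more specific linked object, or
#' subject inheriting the edge from a strict superclass). The result is
#' minimal and regenerates the full edge set under hierarchy closure
#' ([edge_closure()]).
#'
#' @param edges Tibble from [materialize()].
#' @param result Unused (edges carry their redundancy flags); kept so
#'   call sites read naturally.
#' @return Tibble of the non-redundant edges.
#' @export
nonredundant <- function(edges, result = NULL) {
  edges[!edges$redundant, ]
}

#' Regenerate the full entailed edge set from a non-redundant core
#'
#' For every non-redundant edge `(C0, r, D0)` emits `(C, r, D)` for all
#' live `C` below `C0` and `D` above `D0`.
#'
#' @param edges Non-redundant role-edge tibble.
#' @param result The [classify()] result used for the hierarchy.
#' @param live Character vector of classes to range over.
#' @param include_reflexive Keep `(C, r, C)` edges (default `FALSE`).
#' @return Tibble `subject`, `predicate`, `object` (role edges only).
#' @export
edge_closure <- function(edges, result, live, include_reflexive = FALSE) {
  subs <- result$subsumers
  below <- function(C0) Filter(function(C) C0 %in% subs[[C]], live)
  rows <- list()
  role_edges <- edges[edges$predicate != "is_a", ]
  for (i in seq_len(nrow(role_edges))) {
    C0 <- role_edges$subject[i]; r <- role_edges$predicate[i]
    D0 <- role_edges$object[i]
    for (C in below(C0)) {
      for (D in intersect(subs[[D0]], live)) {
        if (!include_reflexive && C == D) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = C, predicate = r, object = D
        )
      }
    }
  }
  out <- if (length(rows)) dplyr::distinct(dplyr::bind_rows(rows)) else {
    tibble::tibble(subject = character(), predicate = character(),
                   object = character())
  }
  out[do.call(order, out[c("predicate", "subject", "object")]), ]
}

#' Write relation edges as TSV
#'
#' @param edges Edge tibble.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_edges_tsv <- function(edges, path) {
  readr::write_tsv(edges, path)
  invisible(path)
}
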