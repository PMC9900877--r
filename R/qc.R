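# Release quality control. The check registry covers what a trait-release
# gate needs: every compiled term classifies under the root attribute
# (ROOT_COVERAGE), no two live classes are entailed equivalent
# (UNIQUENESS for duplicate definitions, CONSISTENCY when the collapse
# comes from an asserted subsumption cycle), obsoletion conventions hold
# (OBSOLETION), and no axiom references an undeclared id (DANGLING_REF).
# The EL fragment has no unsatisfiability, so "consistency" is the
# structural reading: no unintended equivalence between distinct defined
# terms.

qc_checks <- c("ROOT_COVERAGE", "UNIQUENESS", "CONSISTENCY", "OBSOLETION",
               "DANGLING_REF")

qc_violation <- function(check_id, severity, subjects, message) {
  stopifnot(check_id %in% qc_checks, length(subjects) >= 1L)
  tibble::tibble(
    check_id = check_id, severity = severity,
    subjects = list(sort(subjects)), message = message
  )
}

#' Run release quality-control checks
#'
#' @param ont Release ontology (compiled terms merged with references).
#' @param result Its [classify()] result (computed when `NULL`).
#' @param root Root attribute class id every compiled (equivalence-
#'   bearing) live term must classify under.
#' @return A tibble of class `eq_qc_report` with columns `check_id`,
#'   `severity` (`ERROR`/`WARNING`), `subjects` (list column of ids) and
#'   `message`; zero rows for a clean release.
#' @export
run_qc <- function(ont, result = NULL, root) {
  if (!root %in% names(ont$terms)) {
    stop("unknown root id: ", root, call. = FALSE)
  }
  if (is.null(result)) result <- classify(ont)
  v <- list()
  add <- function(...) v[[length(v) + 1L]] <<- qc_violation(...)

  live <- ont_live_ids(ont)
  compiled <- intersect(names(ont_equiv_map(ont)), names(ont$terms))

  # ROOT_COVERAGE: live compiled terms must be subsumed by the root
  for (id in sort(intersect(compiled, live))) {
    if (!root %in% result$subsumers[[id]]) {
      add("ROOT_COVERAGE", "ERROR", id,
          paste0(id, " (", ont_label(ont, id), ") is not classified under ",
                 "the root attribute ", root))
    }
  }

  # UNIQUENESS / CONSISTENCY over equivalence groups of live classes
  told_edges <- ont$axioms |>
    Filter(f = function(a) {
      a$type == "subclass" && expr_is_named(a$sub) && expr_is_named(a$sup)
    }) |>
    lapply(function(a) c(a$sub$id, a$sup$id))
  for (grp in result$equiv) {
    members <- intersect(grp, live)
    if (length(members) < 2L) next
    in_grp <- Filter(function(e) all(e %in% members), told_edges)
    # asserted-subsumption cycle among the members?
    reach <- function(from, to) {
      seen <- from
      repeat {
        nxt <- unique(unlist(lapply(in_grp, function(e) {
          if (e[1] %in% seen) e[2] else NULL
        })))
        nxt <- setdiff(nxt, seen)
        if (!length(nxt)) return(to %in% seen)
        seen <- c(seen, nxt)
        if (to %in% seen) return(TRUE)
      }
    }
    has_cycle <- any(vapply(in_grp, function(e) {
      e[1] != e[2] && reach(e[2], e[1])
    }, logical(1)))
    if (has_cycle) {
      add("CONSISTENCY", "ERROR", members,
          paste0("asserted subsumption cycle collapses ",
                 paste(members, collapse = ", "), " into one class"))
    } else {
      add("UNIQUENESS", "ERROR", members,
          paste0("equivalent attributes: ", paste(members, collapse = ", "),
                 " (no other equivalent attribute may exist)"))
    }
  }

  # OBSOLETION conventions
  for (id in sort(setdiff(names(ont$terms), live))) {
    t <- ont$terms[[id]]
    problems <- character()
    if (!startsWith(t$label %||% "", "obsolete")) {
      problems <- c(problems, "label lacks the 'obsolete ' prefix")
    }
    referencing <- any(vapply(ont$axioms, function(a) {
      id %in% axiom_named_ids(a)
    }, logical(1)))
    if (referencing) {
      problems <- c(problems, "logical axioms still reference the term")
    }
    if (length(problems)) {
      add("OBSOLETION", "ERROR", id,
          paste0(id, ": ", paste(problems, collapse = "; ")))
    }
  }

  # DANGLING_REF
  d <- ont_dangling(ont)
  dangling <- c(d$classes, d$roles)
  if (length(dangling)) {
    add("DANGLING_REF", "ERROR", dangling,
        paste0("axioms reference undeclared id(s): ",
               paste(sort(dangling), collapse = ", ")))
  }

  out <- if (length(v)) dplyr::bind_rows(v) else {
    tibble::tibble(check_id = character(), severity = character(),
                   subjects = list(), message = character())
  }
  class(out) <- c("eq_qc_report", class(out))
  out
}

#' One-row summary of a QC report
#' @param x An `eq_qc_report`.
#' @param ... Unused.
#' @return Tibble with violation counts by severity and check.
#' @export
glance.eq_qc_report <- function(x, ...) {
  tibble::tibble(
    n_violations = nrow(x),
    n_errors = sum(x$severity == "ERROR"),
    n_warnings = sum(x$severity == "WARNING"),
    checks = paste(sort(unique(x$check_id)), collapse = ",")
  )
}

#' Bar chart of QC violations by check
#' @param object An `eq_qc_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eq_qc_report <- function(object, ...) {
  df <- tibble::as_tibble(object[, c("check_id", "severity")])
  if (!nrow(df)) {
    df <- tibble::tibble(check_id = factor(qc_checks, qc_checks), n = 0)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$check_id, y = .data$n)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = NULL, y = "violations",
                      title = "QC report: clean") +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$check_id, fill = .data$severity)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "violations", fill = "severity") +
    ggplot2::theme_minimal()
}
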