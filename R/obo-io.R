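# OBO flat-file subset reader/writer. Supported [Term] tags: id, name,
# def, synonym, subset, is_a, relationship, intersection_of, is_obsolete,
# replaced_by. [Typedef] tags: id, name, is_a, holds_over_chain,
# is_transitive. Semantics follow the standard OBO-to-OWL reading:
# is_a -> SubClassOf between named classes; "relationship: r Y" ->
# SubClassOf(C, r some Y); the full set of intersection_of lines of a
# stanza -> one EquivalentClasses(C, And(...)). Obsolete stanzas must
# carry no logical tags.

obo_known_ignored <- c(
  "format-version", "ontology", "data-version", "date", "saved-by",
  "auto-generated-by", "default-namespace", "subsetdef", "synonymtypedef",
  "remark", "comment", "xref", "namespace", "created_by", "creation_date",
  "alt_id", "property_value", "consider", "idspace", "treat-xrefs-as-is_a"
)

strip_obo_comment <- function(x) stringr::str_squish(sub("\\s*!.*$", "", x))

parse_obo_def <- function(v) {
  m <- regmatches(v, regexec('^"((?:[^"\\\\]|\\\\.)*)"', v))[[1]]
  if (length(m) == 2L) gsub('\\\\(.)', "\\1", m[2]) else strip_obo_comment(v)
}

parse_obo_synonym <- function(v) {
  m <- regmatches(
    v, regexec('^"((?:[^"\\\\]|\\\\.)*)"\\s*(EXACT|BROAD|NARROW|RELATED)?', v)
  )[[1]]
  if (length(m) < 2L) return(NULL)
  scope <- if (length(m) >= 3L && nzchar(m[3])) m[3] else "RELATED"
  list(text = gsub('\\\\(.)', "\\1", m[2]), scope = scope)
}

#' Parse an OBO flat file (subset)
#'
#' @param x OBO document text (single string or character vector of
#'   lines) or a file path.
#' @param prefixes Prefix map for the resulting ontology.
#' @return An `eq_ontology`. Roles referenced by `relationship` /
#'   `intersection_of` lines are auto-declared if no `[Typedef]` stanza
#'   covers them. Unknown tags are skipped with one aggregate warning;
#'   an obsolete stanza carrying logical tags is a hard error.
#' @export
parse_obo <- function(x, prefixes = default_prefixes()) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  ont <- new_ontology(prefixes)
  unknown_tags <- character()

  stanza <- NULL # list(kind=, tags=list of c(tag, value))
  stanzas <- list()
  flush <- function() {
    if (!is.null(stanza)) stanzas[[length(stanzas) + 1L]] <<- stanza
    stanza <<- NULL
  }
  for (ln in lines) {
    ln <- sub("\r$", "", ln)
    if (grepl("^\\s*$", ln)) next
    if (grepl("^\\[(Term|Typedef|Instance)\\]\\s*$", ln)) {
      flush()
      stanza <- list(kind = sub("^\\[(\\w+)\\].*$", "\\1", ln), tags = list())
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z_-]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) next
    if (is.null(stanza)) {
      if (!m[2] %in% obo_known_ignored) unknown_tags <- c(unknown_tags, m[2])
      next
    }
    stanza$tags[[length(stanza$tags) + 1L]] <- c(m[2], m[3])
  }
  flush()

  for (st in stanzas) {
    tags <- st$tags
    tagnames <- vapply(tags, `[`, character(1), 1)
    val <- function(tag) {
      i <- which(tagnames == tag)
      if (length(i)) tags[[i[1]]][2] else NA_character_
    }
    vals <- function(tag) {
      vapply(tags[tagnames == tag], `[`, character(1), 2)
    }
    id <- strip_obo_comment(val("id"))
    if (is.na(id)) next

    if (st$kind == "Typedef") {
      ont <- ont_add_role(ont, id, val("name"))
      for (v in vals("is_a")) {
        ont <- ont_add_axiom(ont, ax_role_sub(id, strip_obo_comment(v)))
      }
      for (v in vals("holds_over_chain")) {
        parts <- strsplit(strip_obo_comment(v), "\\s+")[[1]]
        if (length(parts) != 2L) {
          stop("holds_over_chain must name exactly two roles: ", v, call. = FALSE)
        }
        ont <- ont_add_axiom(ont, ax_role_chain(parts[1], parts[2], id))
      }
      if (identical(strip_obo_comment(val("is_transitive")), "true")) {
        ont <- ont_add_axiom(ont, ax_role_chain(id, id, id))
      }
      extra <- setdiff(unique(tagnames),
                       c("id", "name", "is_a", "holds_over_chain",
                         "is_transitive", obo_known_ignored))
      unknown_tags <- c(unknown_tags, extra)
      next
    }
    if (st$kind != "Term") next

    obsolete <- identical(strip_obo_comment(val("is_obsolete")), "true")
    logical_tags <- intersect(tagnames, c("is_a", "relationship", "intersection_of"))
    if (obsolete && length(logical_tags)) {
      stop("obsolete term ", id, " carries logical tag(s): ",
           paste(unique(logical_tags), collapse = ", "), call. = FALSE)
    }

    syns <- Filter(Negate(is.null), lapply(vals("synonym"), parse_obo_synonym))
    subsets <- strip_obo_comment(vals("subset"))
    ont <- ont_add_term(
      ont, id,
      label = val("name"),
      definition = if (is.na(val("def"))) NA_character_ else parse_obo_def(val("def")),
      synonyms = syns,
      deprecated = obsolete,
      replaced_by = strip_obo_comment(val("replaced_by")),
      subsets = subsets[nzchar(subsets)]
    )

    for (v in vals("is_a")) {
      ont <- ont_add_axiom(ont, ax_subclass(id, strip_obo_comment(v)))
    }
    for (v in vals("relationship")) {
      parts <- strsplit(strip_obo_comment(v), "\\s+")[[1]]
      if (length(parts) != 2L) {
        stop("relationship line needs 'ROLE TARGET': ", v, call. = FALSE)
      }
      if (!parts[1] %in% names(ont$roles)) ont <- ont_add_role(ont, parts[1])
      ont <- ont_add_axiom(ont, ax_subclass(id, c_some(parts[1], parts[2])))
    }
    iparts <- vals("intersection_of")
    if (length(iparts) == 1L) {
      stop("term ", id, ": a single intersection_of line is not a valid ",
           "conjunction", call. = FALSE)
    }
    if (length(iparts) >= 2L) {
      ops <- lapply(iparts, function(v) {
        parts <- strsplit(strip_obo_comment(v), "\\s+")[[1]]
        if (length(parts) == 1L) {
          c_named(parts[1])
        } else if (length(parts) == 2L) {
          if (!parts[1] %in% names(ont$roles)) ont <<- ont_add_role(ont, parts[1])
          c_some(parts[1], parts[2])
        } else {
          stop("malformed intersection_of line: ", v, call. = FALSE)
        }
      })
      ont <- ont_add_axiom(ont, ax_equiv(id, c_and(ops)))
    }
    extra <- setdiff(unique(tagnames),
                     c("id", "name", "def", "synonym", "subset", "is_a",
                       "relationship", "intersection_of", "is_obsolete",
                       "replaced_by", obo_known_ignored))
    unknown_tags <- c(unknown_tags, extra)
  }
  if (length(unknown_tags)) {
    warning("skipped unknown OBO tag(s): ",
            paste(sort(unique(unknown_tags)), collapse = ", "), call. = FALSE)
  }
  ont
}

obo_expr_line <- function(e, tag) {
  if (e$type == "named") return(paste0(tag, ": ", e$id))
  if (e$type == "some" && e$filler$type == "named") {
    return(paste0(tag, ": ", e$role, " ", e$filler$id))
  }
  stop("expression too complex for OBO ", tag, ": ", expr_key(e),
       " (use functional syntax)", call. = FALSE)
}

#' Write an ontology as an OBO flat file (subset)
#'
#' Only named-class and simple existential structure is expressible in
#' OBO; nested conjunctions inside fillers raise an error (serialize such
#' ontologies with [write_functional_syntax()] instead).
#'
#' @param ont An `eq_ontology`.
#' @param path Optional output file.
#' @return OBO text (invisibly when written to `path`).
#' @export
write_obo <- function(ont, path = NULL) {
  esc <- function(x) gsub('"', '\\\\"', x)
  out <- c("format-version: 1.2", "")
  eqm <- ont_equiv_map(ont)
  sub_ax <- Filter(function(a) a$type == "subclass", ont$axioms)
  gci <- Filter(function(a) !expr_is_named(a$sub), sub_ax)
  if (length(gci)) {
    stop("ontology holds ", length(gci), " GCI axiom(s), not expressible in ",
         "OBO; use functional syntax", call. = FALSE)
  }
  sub_by_id <- split(
    sub_ax, vapply(sub_ax, function(a) a$sub$id, character(1))
  )
  for (id in sort(names(ont$terms))) {
    t <- ont$terms[[id]]
    out <- c(out, "[Term]", paste0("id: ", id))
    if (!is.na(t$label %||% NA_character_)) out <- c(out, paste0("name: ", t$label))
    if (!is.na(t$definition %||% NA_character_)) {
      out <- c(out, paste0('def: "', esc(t$definition), '" []'))
    }
    for (s in t$synonyms) {
      out <- c(out, paste0('synonym: "', esc(s$text), '" ', s$scope, " []"))
    }
    for (sb in t$subsets) out <- c(out, paste0("subset: ", sb))
    if (t$deprecated) {
      out <- c(out, "is_obsolete: true")
      if (!is.na(t$replaced_by %||% NA_character_)) {
        out <- c(out, paste0("replaced_by: ", t$replaced_by))
      }
    } else {
      for (a in sub_by_id[[id]] %||% list()) {
        if (expr_is_named(a$sup)) {
          out <- c(out, paste0("is_a: ", a$sup$id))
        } else {
          out <- c(out, obo_expr_line(a$sup, "relationship"))
        }
      }
      if (!is.null(eqm[[id]])) {
        e <- eqm[[id]]
        ops <- if (e$type == "and") e$ops else list(e)
        if (length(ops) < 2L) {
          stop("equivalence for ", id, " is not a conjunction; not expressible ",
               "in OBO", call. = FALSE)
        }
        for (op in ops) out <- c(out, obo_expr_line(op, "intersection_of"))
      }
    }
    out <- c(out, "")
  }
  chains <- Filter(function(a) a$type == "role_chain", ont$axioms)
  role_subs <- Filter(function(a) a$type == "role_sub", ont$axioms)
  for (id in sort(names(ont$roles))) {
    out <- c(out, "[Typedef]", paste0("id: ", id))
    lbl <- ont$roles[[id]]
    if (!is.na(lbl %||% NA_character_)) out <- c(out, paste0("name: ", lbl))
    for (a in role_subs) if (a$sub == id) out <- c(out, paste0("is_a: ", a$sup))
    for (a in chains) {
      if (a$sup == id) {
        if (a$first == id && a$second == id) {
          out <- c(out, "is_transitive: true")
        } else {
          out <- c(out, paste0("holds_over_chain: ", a$first, " ", a$second))
        }
      }
    }
    out <- c(out, "")
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(text))
  }
  text
}
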