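# Design-pattern template compiler: YAML patterns + TSV/tibble filler
# tables -> defined trait classes with generated text and logical axioms.
# Labels and definitions come entirely from each pattern's templates; GCI
# schemas propagate entity part-of structure to the compiled traits.

count_slots <- function(text) lengths(regmatches(text, gregexpr("%s", text, fixed = TRUE)))

validate_text_template <- function(tpl, vars, what, pattern_id) {
  if (is.null(tpl$text) || is.null(tpl$vars)) {
    stop("pattern '", pattern_id, "': ", what, " template needs 'text' and 'vars'",
         call. = FALSE)
  }
  if (count_slots(tpl$text) != length(tpl$vars)) {
    stop("pattern '", pattern_id, "': ", what, " template '", tpl$text, "' has ",
         count_slots(tpl$text), " slot(s) but ", length(tpl$vars), " var(s)",
         call. = FALSE)
  }
  missing <- setdiff(unlist(tpl$vars), vars)
  if (length(missing)) {
    stop("pattern '", pattern_id, "': undeclared var(s) ",
         paste(missing, collapse = ", "), " in ", what, " template", call. = FALSE)
  }
  tpl
}

#' Load a design pattern from YAML
#'
#' A pattern declares an ordered `vars` map (variable name -> range class
#' id; the bound filler must classify under the range), printf-style text
#' templates for the label, definition and synonyms (`%s` slots filled in
#' the order of each template's `vars` list), a logical `equivalent_to`
#' schema in Manchester-like syntax, optional GCI schemas, and the roles
#' the schemas use.
#'
#' @param x Path to a YAML file, or a YAML document string.
#' @return An `eq_pattern`.
#' @export
load_pattern <- function(x) {
  doc <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    yaml::read_yaml(x)
  } else {
    yaml::yaml.load(paste(x, collapse = "\n"))
  }
  pid <- doc$pattern_id %||% stop("pattern is missing 'pattern_id'", call. = FALSE)
  if (is.null(doc$vars) || !length(doc$vars)) {
    stop("pattern '", pid, "' declares no vars", call. = FALSE)
  }
  vars <- vapply(doc$vars, as.character, character(1))
  vnames <- names(vars)

  name_tpl <- validate_text_template(doc$name, vnames, "name", pid)
  def_tpl <- if (!is.null(doc$def)) {
    validate_text_template(doc$def, vnames, "def", pid)
  } else {
    # default wording: attribute of entity, when those two vars exist
    if (all(c("attribute", "entity") %in% vnames)) {
      list(text = "The %s of %s.", vars = list("attribute", "entity"))
    } else {
      stop("pattern '", pid, "' needs a def template", call. = FALSE)
    }
  }
  syn_tpls <- lapply(doc$synonyms %||% list(), function(s) {
    s <- validate_text_template(s, vnames, "synonym", pid)
    s$scope <- toupper(s$scope %||% "EXACT")
    stopifnot(s$scope %in% c("EXACT", "BROAD", "NARROW", "RELATED"))
    s
  })
  if (is.null(doc$equivalent_to)) {
    stop("pattern '", pid, "' has no equivalent_to schema", call. = FALSE)
  }
  equiv_tpl <- validate_text_template(doc$equivalent_to, vnames, "equivalent_to", pid)
  gci_tpls <- lapply(doc$gcis %||% list(), function(g) {
    list(
      sub = validate_text_template(g$sub, vnames, "gci sub", pid),
      sup = validate_text_template(g$sup, vnames, "gci sup", pid)
    )
  })
  roles <- lapply(doc$roles %||% list(), as.character)

  structure(
    list(
      pattern_id = pid, vars = vars,
      name_template = name_tpl, def_template = def_tpl,
      synonym_templates = syn_tpls, equiv_template = equiv_tpl,
      gci_templates = gci_tpls, roles = roles,
      annotations = doc$annotations %||% list()
    ),
    class = "eq_pattern"
  )
}

#' @export
print.eq_pattern <- function(x, ...) {
  cat("<pattern> ", x$pattern_id, " (vars: ",
      paste(names(x$vars), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

instantiate_text <- function(tpl, values) {
  do.call(sprintf, c(list(tpl$text), unname(values[unlist(tpl$vars)])))
}

instantiate_logic <- function(tpl, bindings) {
  parse_class_expression(
    do.call(sprintf, c(list(tpl$text), unname(bindings[unlist(tpl$vars)])))
  )
}

check_row_bindings <- function(p, bindings, refs, refs_result) {
  probs <- character()
  if (!setequal(names(bindings), names(p$vars))) {
    return(paste0(
      "bindings {", paste(names(bindings), collapse = ", "),
      "} do not match pattern vars {", paste(names(p$vars), collapse = ", "), "}"
    ))
  }
  for (v in names(p$vars)) {
    id <- bindings[[v]]
    if (!id %in% names(refs$terms)) {
      probs <- c(probs, paste0("filler ", id, " (var '", v, "') not in references"))
      next
    }
    range <- p$vars[[v]]
    if (range != TOP && !range %in% refs_result$subsumers[[id]]) {
      probs <- c(probs, paste0(
        "filler ", id, " (var '", v, "') is not classified under its range ", range
      ))
    }
  }
  if (length(probs)) paste(probs, collapse = "; ") else NA_character_
}

#' Compile one filler row against a pattern
#'
#' @param p An `eq_pattern`.
#' @param row A one-row data frame (or list) with `defined_class`, one
#'   column per pattern var holding filler ids, and optionally
#'   `label_override`.
#' @param refs Reference ontology the fillers live in.
#' @param refs_result Optional pre-computed [classify()] result for `refs`
#'   (computed on the fly otherwise); used for semantic range checking.
#' @return A list with `term` (term record fields) and `axioms`.
#' @export
compile_row <- function(p, row, refs, refs_result = NULL) {
  stopifnot(inherits(p, "eq_pattern"))
  row <- as.list(row)
  if (is.null(refs_result)) refs_result <- classify(refs)
  bindings <- vapply(names(p$vars), function(v) as.character(row[[v]]), character(1))
  prob <- check_row_bindings(p, bindings, refs, refs_result)
  if (!is.na(prob)) {
    stop("row for ", row$defined_class %||% "<unnamed>", ": ", prob, call. = FALSE)
  }
  labels <- vapply(bindings, function(id) ont_label(refs, id), character(1))
  names(labels) <- names(bindings)

  label <- if (!is.null(row$label_override) && !is.na(row$label_override) &&
               nzchar(row$label_override)) {
    row$label_override
  } else {
    instantiate_text(p$name_template, labels)
  }
  definition <- instantiate_text(p$def_template, labels)
  synonyms <- lapply(p$synonym_templates, function(s) {
    list(text = instantiate_text(s, labels), scope = s$scope)
  })

  axioms <- c(
    list(ax_equiv(row$defined_class, instantiate_logic(p$equiv_template, bindings))),
    lapply(p$gci_templates, function(g) {
      ax_subclass(
        instantiate_logic(g$sub, bindings),
        instantiate_logic(g$sup, bindings)
      )
    })
  )
  list(
    term = new_term(row$defined_class, label = label, definition = definition,
                    synonyms = synonyms),
    axioms = axioms
  )
}

#' Compile a filler table into an ontology fragment
#'
#' Compiles every row, collecting all row-level failures into one
#' aggregate error (not fail-fast). The fragment contains the compiled
#' terms, their equivalence and GCI axioms and the pattern's role
#' declarations — and never an asserted subclass link between two
#' compiled terms: the classification of compiled traits is entirely the
#' reasoner's job.
#'
#' @param p An `eq_pattern`.
#' @param rows Tibble/data frame of filler rows (see [compile_row()]), or
#'   a path to a TSV file with a `defined_class` column plus one column
#'   per pattern var.
#' @param refs Reference ontology.
#' @param refs_result Optional pre-computed classification of `refs`.
#' @return An `eq_ontology` fragment.
#' @export
compile_table <- function(p, rows, refs, refs_result = NULL) {
  stopifnot(inherits(p, "eq_pattern"))
  if (is.character(rows) && length(rows) == 1L) {
    rows <- readr::read_tsv(rows, show_col_types = FALSE, col_types = readr::cols(
      .default = readr::col_character()
    ))
  }
  rows <- tibble::as_tibble(rows)
  if (is.null(refs_result)) refs_result <- classify(refs)

  errors <- character()
  ids <- rows$defined_class
  dup <- ids[duplicated(ids)]
  for (d in unique(dup)) {
    errors <- c(errors, paste0(
      "duplicate defined_class ", d, " in rows ",
      paste(which(ids == d), collapse = " and ")
    ))
  }

  out <- new_ontology(prefixes = refs$prefixes)
  for (rid in names(p$roles)) out <- ont_add_role(out, rid, p$roles[[rid]])

  for (i in seq_len(nrow(rows))) {
    compiled <- tryCatch(
      compile_row(p, rows[i, ], refs, refs_result),
      error = function(e) e
    )
    if (inherits(compiled, "error")) {
      errors <- c(errors, paste0("row ", i, ": ", conditionMessage(compiled)))
      next
    }
    if (!ids[i] %in% names(out$terms)) {
      out$terms[[ids[i]]] <- compiled$term
      for (ax in compiled$axioms) out$axioms[[length(out$axioms) + 1L]] <- ax
    }
  }
  if (length(errors)) {
    stop("compile_table (pattern '", p$pattern_id, "'):\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  out
}

#' Propose trait filler rows from an EQ phenotype ontology
#'
#' Decomposes every phenotype class carrying an equivalence axiom of the
#' abnormality shape (state characteristic + characteristic-of bearer +
#' abnormal modifier) into a candidate entity-attribute filler row: the
#' attribute binding is the nearest attribute-level ancestor of the
#' phenotype's state characteristic (marked via the `attribute_slim`
#' subset in the characteristics ontology, e.g. "increased amount" maps
#' up to "amount"), the entity binding is the bearer. Classes whose
#' bearer is a complex expression, that carry no equivalence axiom, or
#' whose characteristic has no attribute-level ancestor are reported as
#' skipped, not errors. Proposals with identical bindings are merged;
#' every row carries a needs-curation flag.
#'
#' @param pheno Phenotype ontology (EQ-axiomatised).
#' @param characteristics Characteristics ontology with `attribute_slim`
#'   subset markers.
#' @param minter Id minter for proposed defined classes (see
#'   [id_minter()]).
#' @return A list of class `eq_trait_candidates` with `rows` (tibble:
#'   `defined_class`, `attribute`, `entity`, `source_phenotypes`,
#'   `needs_curation`) and `skipped` (tibble: `id`, `reason`).
#' @export
derive_trait_candidates <- function(pheno, characteristics,
                                    minter = id_minter("OBA", 5000000L)) {
  char_res <- classify(characteristics)
  slim <- names(Filter(function(t) "attribute_slim" %in% t$subsets,
                       characteristics$terms))
  nearest_attribute <- function(q) {
    anc <- intersect(char_res$subsumers[[q]] %||% character(), slim)
    if (!length(anc)) return(NA_character_)
    # most specific flagged ancestor(s); ties broken lexicographically
    minimal <- Filter(function(a) {
      !any(vapply(anc, function(b) {
        b != a && a %in% char_res$subsumers[[b]] && !b %in% char_res$subsumers[[a]]
      }, logical(1)))
    }, anc)
    sort(minimal)[1]
  }

  eqm <- ont_equiv_map(pheno)
  rows <- list()
  skipped <- list()
  skip <- function(id, reason) {
    skipped[[length(skipped) + 1L]] <<- tibble::tibble(id = id, reason = reason)
  }
  for (id in sort(names(pheno$terms))) {
    expr <- eqm[[id]]
    if (is.null(expr)) { skip(id, "no equivalence axiom"); next }
    if (expr$type != "and") { skip(id, "definition is not a conjunction"); next }
    quality <- NULL; bearer <- NULL; has_abn <- FALSE
    for (op in expr$ops) {
      if (op$type == "named") {
        quality <- op$id
      } else if (op$type == "some" && op$role == ROLE_CHAR_OF) {
        bearer <- op$filler
      } else if (op$type == "some" && op$role == ROLE_HAS_MODIFIER) {
        has_abn <- TRUE
      }
    }
    if (is.null(quality) || is.null(bearer) || !has_abn) {
      skip(id, "definition does not follow the abnormality shape"); next
    }
    if (bearer$type != "named") {
      skip(id, "bearer is a complex expression"); next
    }
    attr_id <- nearest_attribute(quality)
    if (is.na(attr_id)) {
      skip(id, paste0("characteristic ", quality, " has no attribute-level ancestor"))
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      attribute = attr_id, entity = bearer$id, source = id
    )
  }
  rows <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(attribute = character(), entity = character(), source = character())
  }
  rows <- rows |>
    dplyr::group_by(.data$attribute, .data$entity) |>
    dplyr::summarise(
      source_phenotypes = paste(sort(.data$source), collapse = "|"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$attribute, .data$entity)
  rows$defined_class <- vapply(seq_len(nrow(rows)), function(i) minter(), character(1))
  rows$needs_curation <- TRUE
  rows <- rows[, c("defined_class", "attribute", "entity",
                   "source_phenotypes", "needs_curation")]
  structure(
    list(
      rows = rows,
      skipped = if (length(skipped)) dplyr::bind_rows(skipped) else {
        tibble::tibble(id = character(), reason = character())
      }
    ),
    class = "eq_trait_candidates"
  )
}

#' @export
print.eq_trait_candidates <- function(x, ...) {
  cat("<trait candidates> ", nrow(x$rows), " proposed row(s), ",
      nrow(x$skipped), " skipped class(es)\n", sep = "")
  invisible(x)
}
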