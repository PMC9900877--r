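# OWL functional-syntax subset serializer and parser: the toolkit's
# canonical logical format. Supported constructs: Prefix declarations,
# Class/ObjectProperty declarations, AnnotationAssertion (label,
# definition, synonyms, deprecation, replacement, subsets), SubClassOf
# (GCIs included), EquivalentClasses (named class + one expression),
# SubObjectPropertyOf with optional two-step ObjectPropertyChain,
# ObjectIntersectionOf and ObjectSomeValuesFrom. Anything else —
# unions, complements, universal restrictions, datatypes — is rejected
# with the offending token's position, keeping the toolkit inside the
# EL fragment.

ANN_LABEL <- "rdfs:label"
ANN_DEF <- "IAO:0000115"
ANN_REPLACED <- "IAO:0100001"
ANN_DEPRECATED <- "owl:deprecated"
ANN_SUBSET <- "oboInOwl:inSubset"
ANN_SYNONYM <- c(
  EXACT = "oboInOwl:hasExactSynonym",
  BROAD = "oboInOwl:hasBroadSynonym",
  NARROW = "oboInOwl:hasNarrowSynonym",
  RELATED = "oboInOwl:hasRelatedSynonym"
)

fs_expr <- function(e) {
  switch(e$type,
    named = e$id,
    some = paste0("ObjectSomeValuesFrom(", e$role, " ", fs_expr(e$filler), ")"),
    and = paste0(
      "ObjectIntersectionOf(",
      paste(vapply(e$ops, fs_expr, character(1)), collapse = " "), ")"
    )
  )
}

fs_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Serialize an ontology in OWL functional syntax (subset)
#'
#' Deterministic output: prefixes, declarations, annotations and axioms
#' are each emitted in sorted order, so equal ontologies produce
#' byte-identical documents.
#'
#' @param ont An `eq_ontology`.
#' @param path Optional output file.
#' @return The document text (invisibly when written to `path`).
#' @export
write_functional_syntax <- function(ont, path = NULL) {
  px <- ont$prefixes
  px <- c(px, c(
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    oboInOwl = "http://www.geneontology.org/formats/oboInOwl#",
    xsd = "http://www.w3.org/2001/XMLSchema#"
  )[setdiff(c("rdfs", "oboInOwl", "xsd"), names(px))])
  if (!"owl" %in% names(px)) px[["owl"]] <- "http://www.w3.org/2002/07/owl#"
  lines <- vapply(sort(names(px)), function(p) {
    paste0("Prefix(", p, ":=<", px[[p]], ">)")
  }, character(1))
  lines <- c(lines, "", "Ontology(")

  body <- character()
  for (id in sort(names(ont$terms))) {
    if (startsWith(id, "_:")) next
    body <- c(body, paste0("Declaration(Class(", id, "))"))
  }
  for (id in sort(names(ont$roles))) {
    body <- c(body, paste0("Declaration(ObjectProperty(", id, "))"))
  }
  for (id in sort(names(ont$terms))) {
    if (startsWith(id, "_:")) next
    t <- ont$terms[[id]]
    ann <- function(prop, value) {
      body <<- c(body, paste0("AnnotationAssertion(", prop, " ", id, " ", value, ")"))
    }
    if (!is.na(t$label %||% NA_character_)) ann(ANN_LABEL, fs_quote(t$label))
    if (!is.na(t$definition %||% NA_character_)) ann(ANN_DEF, fs_quote(t$definition))
    for (s in t$synonyms) ann(ANN_SYNONYM[[s$scope]], fs_quote(s$text))
    for (sb in t$subsets) ann(ANN_SUBSET, fs_quote(sb))
    if (t$deprecated) ann(ANN_DEPRECATED, '"true"^^xsd:boolean')
    if (!is.na(t$replaced_by %||% NA_character_)) ann(ANN_REPLACED, t$replaced_by)
  }
  for (id in sort(names(ont$roles))) {
    lbl <- ont$roles[[id]]
    if (!is.na(lbl %||% NA_character_)) {
      body <- c(body, paste0(
        "AnnotationAssertion(", ANN_LABEL, " ", id, " ", fs_quote(lbl), ")"
      ))
    }
  }
  ax_lines <- vapply(ont$axioms, function(a) {
    switch(a$type,
      subclass = paste0("SubClassOf(", fs_expr(a$sub), " ", fs_expr(a$sup), ")"),
      equiv = paste0("EquivalentClasses(", a$id, " ", fs_expr(a$expr), ")"),
      role_sub = paste0("SubObjectPropertyOf(", a$sub, " ", a$sup, ")"),
      role_chain = paste0(
        "SubObjectPropertyOf(ObjectPropertyChain(", a$first, " ", a$second,
        ") ", a$sup, ")"
      )
    )
  }, character(1))
  body <- c(body, sort(unique(ax_lines)))
  lines <- c(lines, body, ")")
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(text))
  }
  text
}

fs_tokenize <- function(text) {
  pattern <- paste0(
    '"(?:[^"\\\\]|\\\\.)*"(?:\\^\\^[A-Za-z][A-Za-z0-9.:_-]*)?', "|",
    "[()]", "|",
    "[^()\\s]+"
  )
  regmatches(text, gregexpr(pattern, text, perl = TRUE))[[1]]
}

#' Parse an OWL functional-syntax document (subset)
#'
#' Inverse of [write_functional_syntax()] on the supported fragment;
#' unsupported constructs are rejected with the token position.
#'
#' @param x Document text or file path.
#' @return An `eq_ontology`.
#' @export
parse_functional_syntax <- function(x) {
  text <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    paste(readLines(x), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  prefixes <- character()
  for (m in regmatches(text, gregexpr(
    "Prefix\\(([A-Za-z][A-Za-z0-9.:_-]*):=<([^>]*)>\\)", text
  ))[[1]]) {
    p <- regmatches(m, regexec(
      "Prefix\\(([A-Za-z][A-Za-z0-9.:_-]*):=<([^>]*)>\\)", m
    ))[[1]]
    prefixes[[p[2]]] <- p[3]
  }
  text <- gsub("Prefix\\([A-Za-z][A-Za-z0-9.:_-]*:=<[^>]*>\\)", "", text)

  toks <- fs_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function(expected = NULL) {
    t <- peek()
    if (is.na(t)) stop("unexpected end of document", call. = FALSE)
    if (!is.null(expected) && !identical(t, expected)) {
      stop("expected '", expected, "' but found '", t, "' at token ", pos,
           call. = FALSE)
    }
    pos <<- pos + 1L
    t
  }
  is_string <- function(t) !is.na(t) && startsWith(t, '"')
  unquote <- function(t) {
    t <- sub("\\^\\^[A-Za-z][A-Za-z0-9.:_-]*$", "", t)
    gsub('\\\\"', '"', substr(t, 2L, nchar(t) - 1L))
  }

  supported_expr_heads <- c("ObjectIntersectionOf", "ObjectSomeValuesFrom")
  reject <- function(t) {
    stop("unsupported construct '", t, "' at token ", pos - 1L,
         " (outside the supported EL fragment)", call. = FALSE)
  }

  parse_expr <- function() {
    t <- take()
    if (t == "ObjectIntersectionOf") {
      take("(")
      ops <- list()
      while (!identical(peek(), ")")) ops <- c(ops, list(parse_expr()))
      take(")")
      if (length(ops) < 2L) stop("ObjectIntersectionOf needs >= 2 operands",
                                 call. = FALSE)
      return(c_and(ops))
    }
    if (t == "ObjectSomeValuesFrom") {
      take("(")
      role <- take()
      filler <- parse_expr()
      take(")")
      return(c_some(role, filler))
    }
    if (grepl("^Object|^Data", t) && !t %in% supported_expr_heads) reject(t)
    c_named(t)
  }

  ont <- new_ontology(if (length(prefixes)) prefixes else default_prefixes())
  ensure_term <- function(id) {
    if (!id %in% names(ont$terms)) ont <<- ont_add_term(ont, id)
  }

  if (identical(peek(), "Ontology")) {
    take("Ontology"); take("(")
    if (!is.na(peek()) && grepl("^<", peek())) take() # ontology IRI
  }

  while (!is.na(peek()) && !identical(peek(), ")")) {
    head <- take()
    switch(head,
      Declaration = {
        take("(")
        kind <- take()
        take("(")
        id <- take()
        take(")"); take(")")
        if (kind == "Class") {
          ensure_term(id)
        } else if (kind == "ObjectProperty") {
          ont <- ont_add_role(ont, id)
        } else if (kind == "AnnotationProperty") {
          # tolerated, carries no structure here
        } else {
          reject(kind)
        }
      },
      AnnotationAssertion = {
        take("(")
        prop <- take()
        subj <- take()
        value <- take()
        take(")")
        ensure_term(subj)
        t <- ont$terms[[subj]]
        if (prop == ANN_LABEL) {
          if (subj %in% names(ont$roles)) {
            ont$roles[[subj]] <- unquote(value)
          } else {
            t$label <- unquote(value)
          }
        } else if (prop == ANN_DEF) {
          t$definition <- unquote(value)
        } else if (prop %in% ANN_SYNONYM) {
          scope <- names(ANN_SYNONYM)[ANN_SYNONYM == prop]
          t$synonyms <- c(t$synonyms, list(list(text = unquote(value), scope = scope)))
        } else if (prop == ANN_SUBSET) {
          t$subsets <- c(t$subsets, unquote(value))
        } else if (prop == ANN_DEPRECATED) {
          t$deprecated <- grepl("true", value)
        } else if (prop == ANN_REPLACED) {
          t$replaced_by <- value
        }
        ont$terms[[subj]] <- t
      },
      SubClassOf = {
        take("(")
        sub <- parse_expr()
        sup <- parse_expr()
        take(")")
        ont <- ont_add_axiom(ont, ax_subclass(sub, sup))
      },
      EquivalentClasses = {
        take("(")
        lhs <- parse_expr()
        rhs <- parse_expr()
        take(")")
        if (expr_is_named(lhs)) {
          ont <- ont_add_axiom(ont, ax_equiv(lhs$id, rhs))
        } else if (expr_is_named(rhs)) {
          ont <- ont_add_axiom(ont, ax_equiv(rhs$id, lhs))
        } else {
          stop("EquivalentClasses needs a named class on one side", call. = FALSE)
        }
      },
      SubObjectPropertyOf = {
        take("(")
        if (identical(peek(), "ObjectPropertyChain")) {
          take(); take("(")
          r1 <- take(); r2 <- take()
          if (!identical(peek(), ")")) {
            stop("role chains longer than 2 are not supported (token ", pos, ")",
                 call. = FALSE)
          }
          take(")")
          sup <- take()
          take(")")
          ont <- ont_add_axiom(ont, ax_role_chain(r1, r2, sup))
        } else {
          sub <- take(); sup <- take()
          take(")")
          ont <- ont_add_axiom(ont, ax_role_sub(sub, sup))
        }
      },
      reject(head)
    )
  }

  # drop accidental term records created for annotation subjects that are
  # really roles
  for (id in names(ont$roles)) ont$terms[[id]] <- NULL
  ont
}

canonical_axiom_set <- function(ont) {
  sort(unique(vapply(ont$axioms, axiom_key, character(1))))
}
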