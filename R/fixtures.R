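# Deterministic generators for all test inputs: curated mini reference
# ontologies (anatomy, chemistry, characteristics), a mini phenotype
# ontology with EQ-axiomatised abnormality classes, seeded random EL
# ontologies, release-defect injectors, and a brute-force reasoning oracle.
# Everything is generated programmatically; nothing is downloaded.
#
# The curated content stands in for Uberon/ChEBI/PATO/MP extracts and is
# synthetic: identifiers follow the look of the real namespaces but the
# ontologies are small hand-built fragments.

ROLE_PART_OF <- "BFO:0000050"
ROLE_CHAR_OF <- "RO:0000052"
ROLE_CHAR_OF_PART_OF <- "RO:0002314"
ROLE_HAS_ROLE <- "RO:0000087"
ROLE_HAS_MODIFIER <- "RO:0002573"

#' Build the curated fixture bundle
#'
#' A fixed-content, fully deterministic set of mini ontologies, patterns
#' and filler tables exercising every component: a mini anatomy with
#' part-of structure (eye in head, ulna in forelimb skeleton, heart and
#' aorta in the cardiovascular system), a mini chemical hierarchy (lysine
#' under amino acid), a characteristics hierarchy with attribute-level
#' terms marked by the `attribute_slim` subset, a phenotype ontology with
#' eight EQ-defined abnormality classes plus two undecomposable ones, the
#' role axioms (characteristic-of o part-of -> characteristic-of-part-of;
#' part-of transitivity), three trait design patterns plus an abnormality
#' pattern, and filler tables for the trait patterns.
#'
#' @return A list of class `eq_fixture_bundle` with elements
#'   `mini_anatomy`, `mini_chemical`, `mini_characteristics`,
#'   `mini_phenotype`, `relations`, `scaffold`, `patterns`, `tables`,
#'   `trait_root`, `stoplist`.
#' @export
build_fixture_bundle <- function() {
  px <- default_prefixes()

  relations <- new_ontology(px) |>
    ont_add_role(ROLE_PART_OF, "part of") |>
    ont_add_role(ROLE_CHAR_OF, "characteristic of") |>
    ont_add_role(ROLE_CHAR_OF_PART_OF, "characteristic of part of") |>
    ont_add_role(ROLE_HAS_ROLE, "has role") |>
    ont_add_role(ROLE_HAS_MODIFIER, "has modifier") |>
    ont_add_axiom(
      ax_role_chain(ROLE_CHAR_OF, ROLE_PART_OF, ROLE_CHAR_OF_PART_OF),
      ax_role_chain(ROLE_PART_OF, ROLE_PART_OF, ROLE_PART_OF)
    )

  anat <- new_ontology(px)
  ae <- "UBERON:0001062"
  anat_terms <- c(
    "UBERON:0001062" = "anatomical entity",
    "UBERON:0000033" = "head",
    "UBERON:0000970" = "eye",
    "UBERON:0000178" = "blood",
    "UBERON:0000980" = "trochanter",
    "UBERON:0001424" = "ulna",
    "UBERON:0001440" = "forelimb skeleton",
    "UBERON:0004535" = "cardiovascular system",
    "UBERON:0000948" = "heart",
    "UBERON:0000947" = "aorta",
    "UBERON:0004086" = "brain ventricle"
  )
  for (id in names(anat_terms)) anat <- ont_add_term(anat, id, anat_terms[[id]])
  for (id in setdiff(names(anat_terms), ae)) {
    anat <- ont_add_axiom(anat, ax_subclass(id, ae))
  }
  anat <- ont_add_axiom(
    anat,
    ax_subclass("UBERON:0000970", c_some(ROLE_PART_OF, "UBERON:0000033")),
    ax_subclass("UBERON:0001424", c_some(ROLE_PART_OF, "UBERON:0001440")),
    ax_subclass("UBERON:0000948", c_some(ROLE_PART_OF, "UBERON:0004535")),
    ax_subclass("UBERON:0000947", c_some(ROLE_PART_OF, "UBERON:0004535"))
  )

  chem <- new_ontology(px)
  chem_terms <- c(
    "CHEBI:24431" = "chemical entity",
    "CHEBI:33709" = "amino acid",
    "CHEBI:25094" = "lysine",
    "CHEBI:17234" = "glucose",
    "CHEBI:50906" = "role",
    "CHEBI:9000001" = "serum metabolite"
  )
  for (id in names(chem_terms)) chem <- ont_add_term(chem, id, chem_terms[[id]])
  chem <- ont_add_axiom(
    chem,
    ax_subclass("CHEBI:33709", "CHEBI:24431"),
    ax_subclass("CHEBI:25094", "CHEBI:33709"),
    ax_subclass("CHEBI:17234", "CHEBI:24431"),
    ax_subclass("CHEBI:9000001", "CHEBI:50906")
  )

  char <- new_ontology(px)
  slim <- "attribute_slim"
  char <- char |>
    ont_add_term("PATO:0000001", "characteristic") |>
    ont_add_term("PATO:0000117", "size", subsets = slim) |>
    ont_add_term("PATO:0000051", "morphology", subsets = slim) |>
    ont_add_term("PATO:0000070", "amount", subsets = slim) |>
    ont_add_term("PATO:0001997", "decreased amount") |>
    ont_add_term("PATO:0000470", "increased amount") |>
    ont_add_term("PATO:0000587", "decreased size") |>
    ont_add_term("PATO:0000586", "increased size") |>
    ont_add_term("PATO:0000460", "abnormal") |>
    ont_add_axiom(
      ax_subclass("PATO:0000117", "PATO:0000001"),
      ax_subclass("PATO:0000051", "PATO:0000001"),
      ax_subclass("PATO:0000070", "PATO:0000001"),
      ax_subclass("PATO:0001997", "PATO:0000070"),
      ax_subclass("PATO:0000470", "PATO:0000070"),
      ax_subclass("PATO:0000587", "PATO:0000117"),
      ax_subclass("PATO:0000586", "PATO:0000117"),
      ax_subclass("PATO:0000460", "PATO:0000001")
    )

  # abnormality EQ shape: state-quality + characteristic-of bearer + abnormal
  abn <- function(quality, bearer) {
    c_and(
      c_named(quality),
      c_some(ROLE_CHAR_OF, bearer),
      c_some(ROLE_HAS_MODIFIER, "PATO:0000460")
    )
  }
  in_blood <- function(chemical) {
    c_and(c_named(chemical), c_some(ROLE_PART_OF, "UBERON:0000178"))
  }

  pheno <- new_ontology(px)
  pheno_terms <- list(
    list("PHEN:0000000", "Phenotypic abnormality", NULL),
    list("PHEN:0000001", "Hypolysinemia", abn("PATO:0001997", in_blood("CHEBI:25094"))),
    list("PHEN:0000002", "Hyperlysinemia", abn("PATO:0000470", in_blood("CHEBI:25094"))),
    list("PHEN:0000003", "Decreased head size", abn("PATO:0000587", "UBERON:0000033")),
    list("PHEN:0000004", "Increased head size", abn("PATO:0000586", "UBERON:0000033")),
    list("PHEN:0000005", "Abnormal head size", abn("PATO:0000117", "UBERON:0000033")),
    list("PHEN:0000006", "Ventriculomegaly", abn("PATO:0000586", "UBERON:0004086")),
    list("PHEN:0000007", "Hyperglycemia", abn("PATO:0000470", in_blood("CHEBI:17234"))),
    list("PHEN:0000008", "Abnormal heart morphology", abn("PATO:0000051", "UBERON:0000948")),
    list("PHEN:0000009", "Seizure", NULL),
    list("PHEN:0000010", "Abnormal behavior", NULL)
  )
  for (t in pheno_terms) {
    pheno <- ont_add_term(pheno, t[[1]], t[[2]])
    if (t[[1]] != "PHEN:0000000") {
      pheno <- ont_add_axiom(pheno, ax_subclass(t[[1]], "PHEN:0000000"))
    }
    if (!is.null(t[[3]])) pheno <- ont_add_axiom(pheno, ax_equiv(t[[1]], t[[3]]))
  }

  scaffold <- new_ontology(px) |>
    ont_add_term("OBA:0000001", "biological attribute") |>
    ont_add_axiom(ax_subclass("PATO:0000001", "OBA:0000001"))

  patterns <- fixture_patterns()

  tables <- list(
    entity_attribute = tibble::tribble(
      ~defined_class, ~attribute, ~entity,
      "OBA:0002360", "PATO:0000117", "UBERON:0000980", # trochanter size
      "OBA:1000001", "PATO:0000117", "UBERON:0000033", # head size
      "OBA:1000002", "PATO:0000117", "UBERON:0000970", # eye size
      "OBA:1000003", "PATO:0000117", "UBERON:0001424", # ulna size
      "OBA:1000004", "PATO:0000117", "UBERON:0001440", # forelimb skeleton size
      "OBA:0002294", "PATO:0000117", "UBERON:0004086", # brain ventricle size
      "OBA:1000005", "PATO:0000051", "UBERON:0000948", # heart morphology
      "OBA:1000006", "PATO:0000051", "UBERON:0000947", # aorta morphology
      "OBA:1000007", "PATO:0000051", "UBERON:0000033"  # head morphology
    ),
    chemical_in_entity_attribute = tibble::tribble(
      ~defined_class, ~attribute, ~chemical, ~location,
      "OBA:2020005",  "PATO:0000070", "CHEBI:25094", "UBERON:0000178", # lysine
      "OBA:VT0000188", "PATO:0000070", "CHEBI:17234", "UBERON:0000178", # glucose
      "OBA:1000008",  "PATO:0000070", "CHEBI:33709", "UBERON:0000178"  # amino acid
    ),
    role_attribute = tibble::tribble(
      ~defined_class, ~attribute, ~role,
      "OBA:2050092", "PATO:0000070", "CHEBI:9000001" # serum metabolite amount
    )
  )

  structure(
    list(
      mini_anatomy = anat,
      mini_chemical = chem,
      mini_characteristics = char,
      mini_phenotype = pheno,
      relations = relations,
      scaffold = scaffold,
      patterns = patterns,
      tables = tables,
      trait_root = "OBA:0000001",
      stoplist = default_stoplist()
    ),
    class = "eq_fixture_bundle"
  )
}

fixture_patterns <- function() {
  list(
    entity_attribute = load_pattern(
      system_pattern("entity_attribute.yaml")
    ),
    chemical_in_entity_attribute = load_pattern(
      system_pattern("chemical_in_entity_attribute.yaml")
    ),
    role_attribute = load_pattern(
      system_pattern("role_attribute.yaml")
    ),
    abnormality = load_pattern(
      system_pattern("abnormality.yaml")
    )
  )
}

system_pattern <- function(name) {
  path <- system.file("extdata", "patterns", name, package = "eqtraits")
  if (path == "") {
    # during development (package loaded via pkgload) fall back to source tree
    path <- file.path("inst", "extdata", "patterns", name)
  }
  path
}

#' Merged reference ontology of the fixture bundle
#'
#' Anatomy + chemistry + characteristics + role axioms + the trait root
#' scaffold, i.e. everything the pattern compiler needs as `refs`.
#'
#' @param bundle A fixture bundle from [build_fixture_bundle()].
#' @return An `eq_ontology`.
#' @export
fixture_refs <- function(bundle) {
  ont_merge(
    bundle$mini_anatomy, bundle$mini_chemical, bundle$mini_characteristics,
    bundle$relations, bundle$scaffold
  )
}

#' Compiled fixture release
#'
#' Compiles every filler table of the bundle with its pattern and merges
#' the fragments with the reference ontologies: the fixture analogue of a
#' full trait-ontology release, ready for classification, relation-graph
#' materialization, linking and QC.
#'
#' @param bundle A fixture bundle from [build_fixture_bundle()].
#' @return An `eq_ontology`.
#' @export
fixture_release <- function(bundle) {
  refs <- fixture_refs(bundle)
  frags <- purrr::imap(bundle$tables, function(tbl, nm) {
    compile_table(bundle$patterns[[nm]], tbl, refs)
  })
  ont_merge(c(list(refs), unname(frags)))
}

#' External trait vocabulary fixture for the matcher
#'
#' Ten external terms: six whose normalized labels equal a compiled trait
#' label, one matching via an exact synonym, one decomposable
#' ("lysine measurement"), and two with no counterpart.
#'
#' @return An `eq_ontology` in the `EXT` namespace.
#' @export
fixture_external_vocab <- function() {
  ext <- new_ontology()
  add <- function(o, id, label, syn = NULL) {
    syns <- if (is.null(syn)) list() else list(list(text = syn, scope = "EXACT"))
    ont_add_term(o, id, label, synonyms = syns)
  }
  ext |>
    add("EXT:0000001", "Trochanter size trait") |>
    add("EXT:0000002", "head size") |>
    add("EXT:0000003", "Eye Size measurement") |>
    add("EXT:0000004", "ulna size trait") |>
    add("EXT:0000005", "Blood glucose amount") |>
    add("EXT:0000006", "heart morphology trait") |>
    add("EXT:0000007", "circulating lysine level", syn = "lysine in blood amount") |>
    add("EXT:0000008", "lysine measurement") |>
    add("EXT:0000009", "xyzzy index") |>
    add("EXT:0000010", "body weight")
}

#' Write the fixture bundle to disk
#'
#' Writes the reference ontologies as OBO, the phenotype/relations/
#' scaffold ontologies as functional syntax (their axioms exceed the OBO
#' subset), the filler tables as TSV and the pattern YAMLs — everything
#' the file-based pipeline needs.
#'
#' @param bundle A fixture bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_files <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_obo(bundle$mini_anatomy, file.path(dir, "mini_anatomy.obo"))
  write_obo(bundle$mini_chemical, file.path(dir, "mini_chemical.obo"))
  write_obo(bundle$mini_characteristics, file.path(dir, "mini_characteristics.obo"))
  write_functional_syntax(bundle$mini_phenotype, file.path(dir, "mini_phenotype.ofn"))
  write_functional_syntax(bundle$relations, file.path(dir, "relations.ofn"))
  write_functional_syntax(bundle$scaffold, file.path(dir, "scaffold.ofn"))
  for (nm in names(bundle$tables)) {
    readr::write_tsv(bundle$tables[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  src <- dirname(system_pattern("entity_attribute.yaml"))
  file.copy(list.files(src, pattern = "[.]yaml$", full.names = TRUE), dir,
            overwrite = TRUE)
  invisible(dir)
}

#' Write a ready-to-run pipeline configuration for the fixture bundle
#'
#' Calls [write_fixture_files()] and adds a `run.yaml` pointing at them.
#'
#' @param bundle A fixture bundle.
#' @param dir Output directory.
#' @return Path of the written config file.
#' @export
write_fixture_config <- function(bundle, dir) {
  write_fixture_files(bundle, dir)
  cfg <- list(
    references = list("mini_chemical.obo", "mini_anatomy.obo",
                      "mini_characteristics.obo"),
    relations = "relations.ofn",
    scaffold = "scaffold.ofn",
    patterns = lapply(names(bundle$tables), function(nm) {
      list(pattern = paste0(nm, ".yaml"), table = paste0(nm, ".tsv"))
    }),
    phenotypes = "mini_phenotype.ofn",
    root = bundle$trait_root,
    roles = list(ROLE_PART_OF, ROLE_CHAR_OF),
    out_dir = "out",
    seed = 1L
  )
  path <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, path)
  path
}

## ---- random ontologies -------------------------------------------------

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Seeded random EL ontology
#'
#' Generates a reproducible ontology within the supported fragment mixing
#' told subsumptions, existential right-hand sides, conjunction right- and
#' left-hand sides (GCIs), existential left-hand sides, role hierarchy and
#' role chain axioms. All existential fillers are drawn from the declared
#' class set so the naive oracle's subexpression closure stays small.
#'
#' @param seed Integer seed.
#' @param n_classes,n_roles,n_axioms Sizes (`n_roles` up to 3).
#' @return An `eq_ontology`.
#' @export
random_el_ontology <- function(seed, n_classes = 15, n_roles = 2, n_axioms = 30) {
  stopifnot(n_classes >= 2, n_roles >= 0, n_roles <= 3, n_axioms >= 1)
  classes <- sprintf("RND:%07d", seq_len(n_classes))
  roles <- if (n_roles > 0) sprintf("RNDR:%07d", seq_len(n_roles)) else character()
  with_seed(seed, {
    ont <- new_ontology()
    for (id in classes) ont <- ont_add_term(ont, id, paste("class", id))
    for (r in roles) ont <- ont_add_role(ont, r, paste("role", r))
    cl <- function() sample(classes, 1)
    rl <- function() sample(roles, 1)
    kinds <- c(
      "sub" = 0.30,
      "ex_rhs" = if (length(roles)) 0.20 else 0,
      "ex_lhs" = if (length(roles)) 0.12 else 0,
      "conj_rhs" = 0.12,
      "conj_lhs" = 0.12,
      "gci_mixed" = if (length(roles)) 0.06 else 0,
      "role_sub" = if (length(roles) >= 2) 0.04 else 0,
      "role_chain" = if (length(roles)) 0.04 else 0
    )
    kinds <- kinds[kinds > 0]
    for (i in seq_len(n_axioms)) {
      k <- sample(names(kinds), 1, prob = kinds)
      ax <- switch(k,
        sub = ax_subclass(cl(), cl()),
        ex_rhs = ax_subclass(cl(), c_some(rl(), cl())),
        ex_lhs = ax_subclass(c_some(rl(), cl()), cl()),
        conj_rhs = ax_subclass(cl(), c_and(cl(), cl())),
        conj_lhs = ax_subclass(c_and(cl(), cl()), cl()),
        gci_mixed = ax_subclass(c_and(cl(), c_some(rl(), cl())), cl()),
        role_sub = {
          rs <- sample(roles, 2)
          ax_role_sub(rs[1], rs[2])
        },
        role_chain = ax_role_chain(rl(), rl(), rl())
      )
      ont$axioms[[length(ont$axioms) + 1L]] <- ax
    }
    ont
  })
}

## ---- brute-force oracle ------------------------------------------------

#' Brute-force subsumption oracle
#'
#' Computes the exact entailed named-class subsumption set of a small EL
#' ontology by exhaustive rule application over the full subexpression
#' closure, re-scanning every rule each round until nothing changes. The
#' implementation is boolean-matrix based and shares no saturation code
#' with [classify()]; it exists purely as an independent reference.
#'
#' @param ont An `eq_ontology` with at most `max_classes` named classes.
#' @param max_classes Size guard (default 40).
#' @return A list with `classes` and `subsumers` in the same shape as the
#'   corresponding fields of [classify()]'s result.
#' @export
brute_force_subsumers <- function(ont, max_classes = 40) {
  named <- names(ont$terms)
  if (length(named) > max_classes) {
    stop("brute_force_subsumers: ", length(named), " classes exceeds the ",
         max_classes, "-class guard", call. = FALSE)
  }

  # subexpression closure
  exprs <- list()
  add_expr <- function(e) {
    for (s in subexpressions(e)) exprs[[expr_key(s)]] <<- s
  }
  for (id in named) add_expr(c_named(id))
  add_expr(c_named(TOP))
  told <- list()   # list(sub_key, sup_key)
  role_subs <- list()
  chains <- list()
  for (ax in ont$axioms) {
    switch(ax$type,
      subclass = {
        add_expr(ax$sub); add_expr(ax$sup)
        told[[length(told) + 1L]] <- c(expr_key(ax$sub), expr_key(ax$sup))
      },
      equiv = {
        add_expr(c_named(ax$id)); add_expr(ax$expr)
        told[[length(told) + 1L]] <- c(ax$id, expr_key(ax$expr))
        told[[length(told) + 1L]] <- c(expr_key(ax$expr), ax$id)
      },
      role_sub = role_subs[[length(role_subs) + 1L]] <- c(ax$sub, ax$sup),
      role_chain = chains[[length(chains) + 1L]] <- c(ax$first, ax$second, ax$sup)
    )
  }

  keys <- names(exprs)
  n <- length(keys)
  idx <- stats::setNames(seq_len(n), keys)
  roles <- unique(c(
    names(ont$roles),
    unlist(lapply(ont$axioms, axiom_role_ids), use.names = FALSE)
  ))

  # S[x, y] == TRUE  means  x [= y (over closure expressions)
  S <- diag(n) > 0
  S[, idx[[TOP]]] <- TRUE
  R <- lapply(stats::setNames(roles, roles), function(r) matrix(FALSE, n, n))

  and_exprs <- Filter(function(e) e$type == "and", exprs)
  some_exprs <- Filter(function(e) e$type == "some", exprs)

  repeat {
    S0 <- S
    R0 <- R
    # told axioms
    for (t in told) S[, idx[[t[2]]]] <- S[, idx[[t[2]]]] | S[, idx[[t[1]]]]
    # conjunction decomposition and composition
    for (e in and_exprs) {
      i <- idx[[expr_key(e)]]
      ops <- vapply(e$ops, expr_key, character(1))
      for (o in ops) S[, idx[[o]]] <- S[, idx[[o]]] | S[, i]
      S[, i] <- S[, i] | apply(S[, idx[ops], drop = FALSE], 1, all)
    }
    # existential introduction and propagation
    for (e in some_exprs) {
      i <- idx[[expr_key(e)]]
      f <- idx[[expr_key(e$filler)]]
      R[[e$role]][, f] <- R[[e$role]][, f] | S[, i]
      S[, i] <- S[, i] | ((R[[e$role]] %*% S[, f]) > 0)
    }
    # role hierarchy
    for (rs in role_subs) R[[rs[2]]] <- R[[rs[2]]] | R[[rs[1]]]
    # role chains
    for (ch in chains) {
      R[[ch[3]]] <- R[[ch[3]]] | ((R[[ch[1]]] %*% R[[ch[2]]]) > 0)
    }
    if (identical(S, S0) && identical(R, R0)) break
  }

  keep <- c(named, TOP)
  subs <- lapply(stats::setNames(named, named), function(C) {
    sort(intersect(keys[S[idx[[C]], ]], keep))
  })
  list(classes = named, subsumers = subs)
}

## ---- defect injection --------------------------------------------------

#' Inject a release defect into an ontology
#'
#' Returns a modified copy carrying exactly one seeded violation of the
#' named kind; the input ontology is untouched. Used to verify that each
#' QC check fires on exactly its defect class.
#'
#' @param ont A release ontology (e.g. [fixture_release()] output).
#' @param defect One of `duplicate_definition`, `orphan_term`,
#'   `obsolete_with_axioms`, `dangling_ref`, `accidental_equivalence`.
#' @param seed Integer controlling which term is corrupted.
#' @return The defective `eq_ontology`.
#' @export
inject_defect <- function(ont, defect, seed = 1L) {
  stopifnot(inherits(ont, "eq_ontology"))
  eqm <- ont_equiv_map(ont)
  compiled <- sort(names(eqm))
  if (!length(compiled) && defect %in%
      c("duplicate_definition", "obsolete_with_axioms", "accidental_equivalence")) {
    stop("ontology has no defined (equivalence-bearing) terms to corrupt", call. = FALSE)
  }
  pick <- function(xs, k = 1L) xs[[1L + (as.integer(seed) + k - 1L) %% length(xs)]]
  switch(defect,
    duplicate_definition = {
      victim <- pick(compiled)
      dup <- "OBA:9900001"
      ont <- ont_add_term(ont, dup,
                          paste0(ont_label(ont, victim), " (duplicate)"))
      ont_add_axiom(ont, ax_equiv(dup, eqm[[victim]]))
    },
    orphan_term = {
      ont <- ont_add_term(ont, "EXT:9000100", "isolated quality")
      ont <- ont_add_term(ont, "OBA:9900002", "orphan attribute")
      ont_add_axiom(ont, ax_equiv(
        "OBA:9900002",
        c_and(c_named("EXT:9000100"),
              c_some(ROLE_CHAR_OF, "UBERON:0000033"))
      ))
    },
    obsolete_with_axioms = {
      victim <- pick(compiled)
      ont$terms[[victim]]$deprecated <- TRUE
      ont
    },
    dangling_ref = {
      ont_add_axiom(ont, ax_subclass(
        "UBERON:0000033", c_some(ROLE_PART_OF, "UBERON:7777777")
      ))
    },
    accidental_equivalence = {
      a <- pick(compiled, 1L)
      b <- pick(setdiff(compiled, a), 2L)
      ont_add_axiom(ont, ax_subclass(a, b), ax_subclass(b, a))
    },
    stop("unknown defect id: ", defect, call. = FALSE)
  )
}
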