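# Composed pipeline: compile -> classify -> relation-graph -> link/match
# -> qc, driven by a YAML run configuration. Artifact files are
# deterministic for a fixed config + inputs; a machine-readable manifest
# records the counts of every stage and whether the run completed.

#' Load an ontology file by extension
#'
#' `.obo` files go through [parse_obo()]; `.ofn`/`.owl`/`.fss` through
#' [parse_functional_syntax()].
#'
#' @param path File path.
#' @param prefixes Prefix map for OBO input.
#' @return An `eq_ontology`.
#' @export
load_ontology_file <- function(path, prefixes = default_prefixes()) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    obo = parse_obo(path, prefixes),
    ofn = ,
    owl = ,
    fss = parse_functional_syntax(path),
    stop("unrecognized ontology file extension: .", ext, call. = FALSE)
  )
}

#' Read a pipeline run configuration
#'
#' YAML with fields: `references` (ordered ontology paths), optional
#' `relations`/`scaffold` ontology paths, `patterns` (list of
#' `{pattern:, table:}` pairs), optional `phenotypes` and `external`
#' ontology paths, `root` class id, `roles` to materialize, `stoplist`,
#' `mint_start`, `out_dir`, `seed`, and optional extra `prefixes`.
#' Relative paths resolve against the config file's directory.
#'
#' @param path YAML file path.
#' @return A list of class `eq_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  cfg$references <- resolve(unlist(cfg$references))
  cfg$relations <- resolve(cfg$relations)
  cfg$scaffold <- resolve(cfg$scaffold)
  cfg$phenotypes <- resolve(cfg$phenotypes)
  cfg$external <- resolve(cfg$external)
  cfg$patterns <- lapply(cfg$patterns, function(p) {
    list(pattern = resolve(p$pattern), table = resolve(p$table))
  })
  cfg$stoplist <- cfg$stoplist %||% default_stoplist()
  cfg$mint_start <- cfg$mint_start %||% 5000000L
  cfg$roles <- unlist(cfg$roles) %||% character()
  cfg$out_dir <- cfg$out_dir %||% file.path(base, "out")
  if (!grepl("^/", cfg$out_dir)) cfg$out_dir <- file.path(base, cfg$out_dir)
  cfg$seed <- cfg$seed %||% 1L
  prefixes <- default_prefixes()
  if (length(cfg$prefixes)) prefixes[names(cfg$prefixes)] <- unlist(cfg$prefixes)
  cfg$prefix_map <- prefixes
  structure(cfg, class = "eq_run_config")
}

pipeline_log <- function(...) message("[eqtraits] ", ...)

#' Run the composed pipeline
#'
#' Compiles every pattern/table pair against the merged references,
#' classifies the release, materializes the relation graph, links
#' phenotypes (when configured), generates match candidates for an
#' external vocabulary (when configured), and runs QC. Artifacts are
#' written to the configured output directory; a `manifest.json` records
#' per-stage counts and completeness.
#'
#' @param cfg An `eq_run_config` (or a path to one).
#' @return Invisibly, a list with `status` (0 clean, 1 QC error,
#'   2 input/parse error), `artifacts` (paths) and `counts`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  counts <- list()
  status <- 0L
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  fail <- function(stage, e) {
    pipeline_log("ERROR in ", stage, ": ", conditionMessage(e))
    jsonlite::write_json(
      list(complete = FALSE, failed_stage = stage,
           error = conditionMessage(e), counts = counts,
           artifacts = as.list(artifacts)),
      manifest_path, auto_unbox = TRUE, pretty = TRUE
    )
    invisible(list(status = 2L, artifacts = artifacts, counts = counts))
  }

  inputs <- tryCatch({
    refs <- ont_merge(lapply(cfg$references, load_ontology_file,
                             prefixes = cfg$prefix_map))
    for (extra in c(cfg$relations, cfg$scaffold)) {
      refs <- ont_merge(refs, load_ontology_file(extra, cfg$prefix_map))
    }
    pats <- lapply(cfg$patterns, function(p) {
      list(pattern = load_pattern(p$pattern), table = p$table)
    })
    list(refs = refs, pats = pats)
  }, error = function(e) e)
  if (inherits(inputs, "error")) return(fail("load", inputs))
  refs <- inputs$refs
  pipeline_log("loaded ", length(cfg$references), " reference ontolog(ies): ",
               length(refs$terms), " classes")

  release <- tryCatch({
    refs_result <- classify(refs)
    frags <- lapply(inputs$pats, function(p) {
      compile_table(p$pattern, p$table, refs, refs_result)
    })
    ont_merge(c(list(refs), frags))
  }, error = function(e) e)
  if (inherits(release, "error")) return(fail("compile", release))
  counts$compiled_terms <- length(names(ont_equiv_map(release)))
  pipeline_log("compiled ", counts$compiled_terms, " defined terms")

  ofn_path <- file.path(cfg$out_dir, "compiled.ofn")
  write_functional_syntax(release, ofn_path)
  artifacts <- c(artifacts, ofn_path)

  result <- classify(release)
  taxonomy <- purrr::map_dfr(result$classes, function(C) {
    ps <- result$direct_parents[[C]]
    if (!length(ps)) return(NULL)
    tibble::tibble(child = C, parent = ps)
  }) |> dplyr::arrange(.data$child, .data$parent)
  tax_path <- file.path(cfg$out_dir, "taxonomy.tsv")
  readr::write_tsv(taxonomy, tax_path)
  artifacts <- c(artifacts, tax_path)
  counts$taxonomy_edges <- nrow(taxonomy)
  pipeline_log("classified: ", nrow(taxonomy), " direct subsumption edges")

  edges <- materialize(release, result, roles = intersect(cfg$roles, names(release$roles)))
  edges_path <- file.path(cfg$out_dir, "edges.tsv")
  write_edges_tsv(edges, edges_path)
  artifacts <- c(artifacts, edges_path)
  counts$relation_edges <- nrow(edges)
  pipeline_log("materialized ", nrow(edges), " relation edges")

  if (!is.null(cfg$phenotypes)) {
    link <- tryCatch({
      pheno <- load_ontology_file(cfg$phenotypes, cfg$prefix_map)
      link_phenotypes(release, pheno)
    }, error = function(e) e)
    if (inherits(link, "error")) return(fail("link", link))
    sssom_path <- file.path(cfg$out_dir, "links.sssom.tsv")
    write_sssom(
      link$mappings,
      metadata = list(
        mapping_set_id = "phenotype-to-trait-links",
        mapping_date = "1970-01-01"
      ),
      path = sssom_path
    )
    artifacts <- c(artifacts, sssom_path)
    counts$phenotype_links <- link$summary$links
    counts$phenotypes_under_traits <- link$summary$classes_under_root
    pipeline_log("linked ", link$summary$links, " phenotype mappings")
  }

  if (!is.null(cfg$external)) {
    cand <- tryCatch({
      external <- load_ontology_file(cfg$external, cfg$prefix_map)
      ref_onts <- lapply(cfg$references, load_ontology_file,
                         prefixes = cfg$prefix_map)
      pats <- lapply(inputs$pats, function(p) p$pattern)
      generate_candidates(external, release, ref_onts, pats, cfg$stoplist)
    }, error = function(e) e)
    if (inherits(cand, "error")) return(fail("match", cand))
    cand_path <- file.path(cfg$out_dir, "candidates.tsv")
    readr::write_tsv(cand, cand_path)
    artifacts <- c(artifacts, cand_path)
    counts$match_candidates <- nrow(cand)
    pipeline_log("generated ", nrow(cand), " match candidates")
  }

  report <- run_qc(release, result, root = cfg$root)
  qc_path <- file.path(cfg$out_dir, "qc.json")
  jsonlite::write_json(
    list(
      n_violations = nrow(report),
      violations = lapply(seq_len(nrow(report)), function(i) {
        list(check_id = report$check_id[i], severity = report$severity[i],
             subjects = report$subjects[[i]], message = report$message[i])
      })
    ),
    qc_path, auto_unbox = TRUE, pretty = TRUE
  )
  artifacts <- c(artifacts, qc_path)
  counts$qc_violations <- nrow(report)
  pipeline_log("qc: ", nrow(report), " violation(s)")
  if (any(report$severity == "ERROR")) status <- 1L

  jsonlite::write_json(
    list(complete = TRUE, status = status, counts = counts,
         artifacts = as.list(artifacts)),
    manifest_path, auto_unbox = TRUE, pretty = TRUE
  )
  artifacts <- c(artifacts, manifest_path)
  invisible(list(status = status, artifacts = artifacts, counts = counts))
}
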