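# Lexical alignment of external trait vocabularies: normalization-based
# exact matching on labels and EXACT synonyms (the Match step), and
# reference-ontology decomposition of unmatched labels into pattern
# bindings for curator review (the Sync step). Curation decisions travel
# through a plain TSV review file; accepted decompositions feed the
# pattern compiler (the Compile step).

#' Default stop-word list for label normalization
#'
#' Measurement/trait boilerplate words, with plurals; configurable at
#' every call site.
#'
#' @return Character vector.
#' @export
default_stoplist <- function() c("measurement", "measurements", "trait", "traits")

#' Normalize a label into an ordered token list
#'
#' Lowercases, strips punctuation, tokenizes on whitespace and removes
#' stop words. Deterministic and idempotent on its own output.
#'
#' @param text Character vector of labels.
#' @param stoplist Words to drop after tokenization.
#' @return For a single label, a character vector of tokens; for several,
#'   a list of such vectors.
#' @export
#' @examples
#' normalize_label("Lysine measurement")
normalize_label <- function(text, stoplist = default_stoplist()) {
  one <- function(x) {
    x <- stringr::str_to_lower(x)
    x <- stringr::str_replace_all(x, "[^a-z0-9]+", " ")
    toks <- stringr::str_split_1(stringr::str_squish(x), " ")
    toks <- toks[nzchar(toks) & !toks %in% stoplist]
    toks
  }
  if (length(text) == 1L) one(text) else lapply(text, one)
}

norm_key <- function(text, stoplist) {
  paste(normalize_label(text, stoplist), collapse = " ")
}

# normalized-string -> ids lookup over labels and EXACT synonyms
build_lexical_index <- function(ont, stoplist, live_only = TRUE, ids = NULL) {
  if (is.null(ids)) ids <- if (live_only) ont_live_ids(ont) else names(ont$terms)
  entries <- list()
  for (id in ids) {
    t <- ont$terms[[id]]
    if (!is.na(t$label %||% NA_character_)) {
      entries[[length(entries) + 1L]] <-
        tibble::tibble(key = norm_key(t$label, stoplist), id = id, via = "label")
    }
    for (s in t$synonyms) {
      if (identical(s$scope, "EXACT")) {
        entries[[length(entries) + 1L]] <-
          tibble::tibble(key = norm_key(s$text, stoplist), id = id, via = "synonym")
      }
    }
  }
  if (!length(entries)) {
    return(tibble::tibble(key = character(), id = character(), via = character()))
  }
  dplyr::distinct(dplyr::bind_rows(entries))
}

match_candidate_row <- function(external_id, external_label, kind = "NONE",
                                matched_trait = NA_character_,
                                matched_trait_label = NA_character_,
                                pattern_id = NA_character_,
                                bindings = NA_character_,
                                note = NA_character_) {
  tibble::tibble(
    external_id = external_id, external_label = external_label, kind = kind,
    matched_trait = matched_trait, matched_trait_label = matched_trait_label,
    pattern_id = pattern_id, bindings = bindings, note = note,
    decision = "PENDING"
  )
}

#' Lexically match external terms against trait terms
#'
#' An external term gets kind `EXACT_LABEL` when its normalized label
#' equals a unique trait's normalized label; `EXACT_SYNONYM` when its
#' normalized label or one of its normalized EXACT synonyms equals a
#' trait label/EXACT synonym (synonym-mediated); `NONE` otherwise. A
#' normalized string resolving to more than one trait yields `NONE` with
#' an ambiguity note rather than an arbitrary pick.
#'
#' @param external,traits Ontologies with labels (EXACT synonyms used
#'   when present).
#' @param stoplist Stop words for normalization.
#' @param trait_ids Trait terms to match against. Defaults to the
#'   compiled (equivalence-bearing) terms of `traits` when any exist —
#'   so a release that still contains its reference ontologies only
#'   offers actual trait terms as match targets — and to all live terms
#'   otherwise.
#' @return Tibble of match candidates (one row per live external term)
#'   with columns `external_id`, `external_label`, `kind`,
#'   `matched_trait`, `matched_trait_label`, `pattern_id`, `bindings`,
#'   `note`, `decision`.
#' @export
match_terms <- function(external, traits, stoplist = default_stoplist(),
                        trait_ids = NULL) {
  if (is.null(trait_ids)) {
    compiled <- intersect(names(ont_equiv_map(traits)), ont_live_ids(traits))
    trait_ids <- if (length(compiled)) compiled else ont_live_ids(traits)
  }
  index <- build_lexical_index(traits, stoplist, ids = trait_ids)
  lookup <- function(key) {
    hit <- index[index$key == key & nzchar(key), ]
    unique(hit$id)
  }
  out <- list()
  for (id in sort(ont_live_ids(external))) {
    t <- external$terms[[id]]
    label <- t$label %||% ""
    keys <- tibble::tibble(key = norm_key(label, stoplist), via = "label")
    for (s in t$synonyms) {
      if (identical(s$scope, "EXACT")) {
        keys <- dplyr::bind_rows(
          keys, tibble::tibble(key = norm_key(s$text, stoplist), via = "synonym")
        )
      }
    }
    row <- match_candidate_row(id, label)
    for (i in seq_len(nrow(keys))) {
      hits <- lookup(keys$key[i])
      if (length(hits) == 1L) {
        trait_via_label <- index$via[index$key == keys$key[i] & index$id == hits][1]
        kind <- if (keys$via[i] == "label" && trait_via_label == "label") {
          "EXACT_LABEL"
        } else {
          "EXACT_SYNONYM"
        }
        row <- match_candidate_row(
          id, label, kind = kind, matched_trait = hits,
          matched_trait_label = ont_label(traits, hits)
        )
        break
      }
      if (length(hits) > 1L) {
        row <- match_candidate_row(
          id, label,
          note = paste0("ambiguous: normalized form matches ",
                        paste(sort(hits), collapse = ", "))
        )
        break
      }
    }
    out[[length(out) + 1L]] <- row
  }
  if (!length(out)) match_candidate_row(character(), character())[0, ] else {
    dplyr::bind_rows(out)
  }
}

serialize_bindings <- function(b) {
  paste(paste0(names(b), "=", unname(b)), collapse = "|")
}

deserialize_bindings <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character())
  kv <- strsplit(strsplit(s, "|", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(
    vapply(kv, `[`, character(1), 2),
    vapply(kv, `[`, character(1), 1)
  )
}

#' Decompose an external label into pattern bindings
#'
#' Scans the normalized label for maximal contiguous token runs equal to
#' a reference term's normalized label or EXACT synonym, trying the
#' reference ontologies in their configured order (earlier ontologies
#' claim tokens first; within an ontology, longest match wins, then
#' leftmost, non-overlapping). Matched reference terms are then assigned
#' to pattern variable slots by semantic range (a chemical-ranged
#' variable takes the hit from the chemical reference, etc.); the pattern
#' filling the most slots wins, ties resolved by pattern order.
#'
#' @param label External term label.
#' @param refs Ordered list of reference ontologies.
#' @param patterns List of `eq_pattern`s to propose against.
#' @param stoplist Stop words.
#' @param refs_results Optional list of pre-computed classifications for
#'   `refs` (same order).
#' @return A one-row candidate tibble with kind `DECOMPOSITION` (at
#'   least one slot filled) or `NONE`.
#' @export
propose_decomposition <- function(label, refs, patterns,
                                  stoplist = default_stoplist(),
                                  refs_results = NULL) {
  toks <- normalize_label(label, stoplist)
  if (!length(toks)) {
    return(match_candidate_row(NA_character_, label, note = "empty after normalization"))
  }
  if (is.null(refs_results)) refs_results <- lapply(refs, classify)

  claimed <- rep(FALSE, length(toks))
  hits <- list() # list of (id, ref_index) in claim order
  for (ri in seq_along(refs)) {
    index <- build_lexical_index(refs[[ri]], stoplist)
    repeat {
      best <- NULL
      for (len in rev(seq_len(length(toks)))) {
        for (start in seq_len(length(toks) - len + 1L)) {
          span <- start:(start + len - 1L)
          if (any(claimed[span])) next
          key <- paste(toks[span], collapse = " ")
          ids <- unique(index$id[index$key == key])
          if (length(ids) == 1L) { best <- list(span = span, id = ids); break }
        }
        if (!is.null(best)) break
      }
      if (is.null(best)) break
      claimed[best$span] <- TRUE
      hits[[length(hits) + 1L]] <- list(id = best$id, ref = ri)
    }
  }
  if (!length(hits)) {
    return(match_candidate_row(NA_character_, label, note = "no reference hit"))
  }

  fits_range <- function(id, ref_i, range) {
    if (range == TOP) return(TRUE)
    range %in% (refs_results[[ref_i]]$subsumers[[id]] %||% character())
  }
  best <- NULL
  for (p in patterns) {
    bindings <- character()
    used <- logical(length(hits))
    for (v in names(p$vars)) {
      for (hi in seq_along(hits)) {
        if (used[hi]) next
        if (fits_range(hits[[hi]]$id, hits[[hi]]$ref, p$vars[[v]])) {
          bindings[[v]] <- hits[[hi]]$id
          used[hi] <- TRUE
          break
        }
      }
    }
    if (length(bindings) &&
        (is.null(best) || length(bindings) > length(best$bindings))) {
      best <- list(pattern = p, bindings = bindings)
    }
  }
  if (is.null(best)) {
    return(match_candidate_row(NA_character_, label,
                               note = "reference hits fit no pattern slot"))
  }
  match_candidate_row(
    NA_character_, label, kind = "DECOMPOSITION",
    pattern_id = best$pattern$pattern_id,
    bindings = serialize_bindings(best$bindings)
  )
}

#' Full Match + Sync candidate generation
#'
#' Runs exact matching first and EQ decomposition only for external
#' terms that found no exact match, mirroring the Match-before-Sync step
#' order. No candidate is ever both exact and decomposed.
#'
#' @inheritParams match_terms
#' @param refs Ordered list of reference ontologies for decomposition.
#' @param patterns Patterns for decomposition proposals.
#' @return Candidate tibble covering every live external term.
#' @export
generate_candidates <- function(external, traits, refs, patterns,
                                stoplist = default_stoplist()) {
  exact <- match_terms(external, traits, stoplist)
  refs_results <- lapply(refs, classify)
  out <- list()
  for (i in seq_len(nrow(exact))) {
    row <- exact[i, ]
    if (row$kind == "NONE" && is.na(row$note)) {
      dec <- propose_decomposition(row$external_label, refs, patterns,
                                   stoplist, refs_results)
      dec$external_id <- row$external_id
      row <- dec
    }
    out[[length(out) + 1L]] <- row
  }
  dplyr::bind_rows(out)
}

#' Apply curator review decisions to match candidates
#'
#' @param candidates Candidate tibble from [match_terms()] /
#'   [generate_candidates()].
#' @param review Tibble (or TSV path) with columns `external_id`,
#'   `decision` (`ACCEPTED`/`REJECTED`) and optional `note`.
#' @param external Ontology the external ids come from (for labels).
#' @param minter Id minter for accepted decompositions.
#' @return A list with `mappings` (SSSOM tibble of accepted exact
#'   matches, justification LexicalMatching) and `fillers` (tibble of
#'   filler rows for the pattern compiler, one per accepted
#'   decomposition, with freshly minted ids; columns `defined_class`,
#'   `pattern_id`, `bindings` plus one column per bound var).
#' @export
apply_review <- function(candidates, review, external,
                         minter = id_minter("OBA", 5000000L)) {
  if (is.character(review) && length(review) == 1L) {
    review <- readr::read_tsv(review, show_col_types = FALSE)
  }
  review <- tibble::as_tibble(review)
  unknown <- setdiff(review$external_id, candidates$external_id)
  if (length(unknown)) {
    stop("review decisions for unknown candidate(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  merged <- dplyr::left_join(
    candidates |> dplyr::select(-"decision"),
    review |> dplyr::select("external_id", "decision"),
    by = "external_id"
  )
  merged$decision[is.na(merged$decision)] <- "PENDING"

  acc <- merged[merged$decision == "ACCEPTED", ]
  mappings <- list()
  fillers <- list()
  for (i in seq_len(nrow(acc))) {
    row <- acc[i, ]
    if (row$kind %in% c("EXACT_LABEL", "EXACT_SYNONYM")) {
      mappings[[length(mappings) + 1L]] <- sssom_row(
        subject_id = row$external_id,
        subject_label = row$external_label,
        predicate_id = "skos:exactMatch",
        object_id = row$matched_trait,
        object_label = row$matched_trait_label,
        mapping_justification = "semapv:LexicalMatching"
      )
    } else if (row$kind == "DECOMPOSITION") {
      b <- deserialize_bindings(row$bindings)
      fillers[[length(fillers) + 1L]] <- tibble::as_tibble(c(
        list(defined_class = minter(), pattern_id = row$pattern_id,
             bindings = row$bindings, source_label = row$external_label),
        as.list(b)
      ))
    }
  }
  list(
    mappings = if (length(mappings)) dplyr::bind_rows(mappings) else empty_sssom(),
    fillers = if (length(fillers)) dplyr::bind_rows(fillers) else {
      tibble::tibble(defined_class = character(), pattern_id = character(),
                     bindings = character(), source_label = character())
    }
  )
}
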