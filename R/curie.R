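#' Default prefix map
#'
#' Prefix-to-URI-base map following OBO PURL conventions
#' (`http://purl.obolibrary.org/obo/<PREFIX>_`), plus the handful of
#' non-OBO namespaces the toolkit emits (skos, semapv, owl).
#'
#' @param extra Named character vector of additional prefix -> URI base
#'   entries; entries here override the defaults.
#' @return Named character vector mapping prefix to URI base.
#' @export
#' @examples
#' default_prefixes()[["OBA"]]
default_prefixes <- function(extra = character()) {
  obo <- c(
    "OBA", "PATO", "UBERON", "CHEBI", "BFO", "RO", "GO", "PR", "HP", "MP",
    "VT", "EFO", "IAO", "PHEN", "EXT"
  )
  base <- stats::setNames(
    paste0("http://purl.obolibrary.org/obo/", obo, "_"),
    obo
  )
  base <- c(
    base,
    skos = "http://www.w3.org/2004/02/skos/core#",
    semapv = "https://w3id.org/semapv/vocab/",
    owl = "http://www.w3.org/2002/07/owl#"
  )
  if (length(extra)) base[names(extra)] <- extra
  base
}

#' Parse a CURIE or PURL into its components
#'
#' Accepts either a compact identifier (`"OBA:0002360"`) or a full PURL
#' (`"http://purl.obolibrary.org/obo/OBA_2020005"`) resolvable against the
#' supplied prefix map. The local part is kept verbatim, so source-tagged
#' identifiers such as `OBA:VT0000188` round-trip losslessly.
#'
#' @param text A single identifier string (CURIE or expanded URI).
#' @param prefixes Named character vector, prefix -> URI base.
#' @return An object of class `eq_curie` with fields `prefix` and `local`.
#' @export
#' @examples
#' parse_curie("OBA:0002360")
#' parse_curie("http://purl.obolibrary.org/obo/OBA_2020005")
parse_curie <- function(text, prefixes = default_prefixes()) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (grepl("^https?://", text)) {
    hit <- NULL
    for (p in names(prefixes)) {
      base <- prefixes[[p]]
      if (startsWith(text, base)) {
        cand <- list(prefix = p, local = substring(text, nchar(base) + 1L))
        # prefer the longest matching base
        if (is.null(hit) || nchar(base) > nchar(prefixes[[hit$prefix]])) hit <- cand
      }
    }
    if (is.null(hit)) {
      stop("parse_curie: no declared prefix matches URI <", text, ">", call. = FALSE)
    }
    return(new_curie(hit$prefix, hit$local))
  }
  m <- regmatches(text, regexec("^([A-Za-z_][A-Za-z0-9_.-]*):(\\S+)$", text))[[1]]
  if (length(m) != 3L) {
    stop("parse_curie: '", text, "' is not a CURIE of the form PREFIX:local", call. = FALSE)
  }
  if (!m[2] %in% names(prefixes)) {
    stop("parse_curie: unknown prefix '", m[2], "' in '", text, "'", call. = FALSE)
  }
  new_curie(m[2], m[3])
}

new_curie <- function(prefix, local) {
  structure(list(prefix = prefix, local = local), class = "eq_curie")
}

#' Expand a CURIE to its PURL form
#'
#' @param x An `eq_curie` or a `"PREFIX:local"` string.
#' @param prefixes Named character vector, prefix -> URI base.
#' @return The expanded URI string.
#' @export
expand_curie <- function(x, prefixes = default_prefixes()) {
  if (is.character(x)) x <- parse_curie(x, prefixes)
  stopifnot(inherits(x, "eq_curie"))
  if (!x$prefix %in% names(prefixes)) {
    stop("expand_curie: unknown prefix '", x$prefix, "'", call. = FALSE)
  }
  paste0(prefixes[[x$prefix]], x$local)
}

#' Render a CURIE as a compact string
#'
#' @param x An `eq_curie` object.
#' @return `"PREFIX:local"`.
#' @export
curie_string <- function(x) {
  stopifnot(inherits(x, "eq_curie"))
  paste0(x$prefix, ":", x$local)
}

#' @export
print.eq_curie <- function(x, ...) {
  cat("<curie> ", curie_string(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.eq_curie <- function(x, ...) curie_string(x)

curie_prefix <- function(id) sub(":.*$", "", id)

#' Sequential identifier minter
#'
#' Returns a closure that mints fresh CURIEs `PREFIX:NNNNNNN` with
#' zero-padded 7-digit numeric locals starting at `start`. Source-tagged
#' identifiers (e.g. a `VT`-prefixed local) are never minted here; they are
#' preserved verbatim wherever they enter the system.
#'
#' @param prefix Namespace prefix for minted ids.
#' @param start First integer to use.
#' @return A function() returning one fresh id string per call.
#' @export
#' @examples
#' mint <- id_minter("OBA", 5000000)
#' mint(); mint()
id_minter <- function(prefix = "OBA", start = 5000000L) {
  n <- as.integer(start) - 1L
  function() {
    n <<- n + 1L
    sprintf("%s:%07d", prefix, n)
  }
}
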