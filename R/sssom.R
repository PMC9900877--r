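# SSSOM (Simple Standard for Sharing Ontological Mappings) TSV writer and
# helpers. Fixed column order; metadata as a commented YAML-style header
# block; absent confidence is an empty cell, never zero.

sssom_columns <- c(
  "subject_id", "subject_label", "predicate_id", "object_id", "object_label",
  "mapping_justification", "confidence"
)

sssom_justifications <- c(
  "semapv:LexicalMatching", "semapv:LogicalReasoning", "semapv:ManualMappingCuration"
)

#' Construct one SSSOM mapping row
#'
#' @param subject_id,subject_label,predicate_id,object_id,object_label
#'   Mapping fields (ids as CURIE strings).
#' @param mapping_justification One of `semapv:LexicalMatching`,
#'   `semapv:LogicalReasoning`, `semapv:ManualMappingCuration`.
#' @param confidence Number in `[0, 1]`, or `NA` for absent.
#' @return One-row tibble.
#' @export
sssom_row <- function(subject_id, subject_label, predicate_id, object_id,
                      object_label, mapping_justification,
                      confidence = NA_real_) {
  if (!mapping_justification %in% sssom_justifications) {
    stop("unsupported mapping_justification: ", mapping_justification, call. = FALSE)
  }
  stopifnot(is.na(confidence) || (confidence >= 0 && confidence <= 1))
  tibble::tibble(
    subject_id = subject_id, subject_label = subject_label,
    predicate_id = predicate_id, object_id = object_id,
    object_label = object_label,
    mapping_justification = mapping_justification,
    confidence = as.numeric(confidence)
  )
}

empty_sssom <- function() {
  tibble::tibble(
    subject_id = character(), subject_label = character(),
    predicate_id = character(), object_id = character(),
    object_label = character(), mapping_justification = character(),
    confidence = numeric()
  )
}

#' Write mappings as SSSOM TSV
#'
#' @param rows Tibble of mapping rows (see [sssom_row()]).
#' @param metadata Named list written as a commented header block.
#' @param path Optional output file; when `NULL` the TSV text is
#'   returned.
#' @return The TSV text, invisibly when written to `path`.
#' @export
write_sssom <- function(rows, metadata = list(), path = NULL) {
  rows <- tibble::as_tibble(rows)
  stopifnot(all(sssom_columns %in% names(rows)) || nrow(rows) == 0)
  header <- character()
  for (k in names(metadata)) {
    header <- c(header, paste0("# ", k, ": ", metadata[[k]]))
  }
  lines <- c(header, paste(sssom_columns, collapse = "\t"))
  if (nrow(rows)) {
    rows <- rows[do.call(order, rows[c("subject_id", "predicate_id", "object_id")]), ]
    for (i in seq_len(nrow(rows))) {
      cells <- vapply(sssom_columns, function(col) {
        v <- rows[[col]][i]
        if (is.na(v)) "" else as.character(v)
      }, character(1))
      lines <- c(lines, paste(cells, collapse = "\t"))
    }
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(text))
  }
  text
}

#' Read an SSSOM TSV written by [write_sssom()]
#'
#' @param path File path.
#' @return Tibble of mapping rows.
#' @export
read_sssom <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  readr::read_tsv(I(paste(lines, collapse = "\n")), show_col_types = FALSE,
                  col_types = readr::cols(
                    confidence = readr::col_double(),
                    .default = readr::col_character()
                  ))
}
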