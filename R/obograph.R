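# OBO Graph JSON writer: the nodes-and-edges view of an ontology plus a
# set of materialized relation edges.

#' Write an ontology and relation edges as OBO Graph JSON
#'
#' Nodes carry `id` (expanded to its PURL when the prefix is declared),
#' `lbl` and a deprecation flag; edges carry `sub`/`pred`/`obj`. Output
#' ordering is deterministic (sorted by id / edge triple).
#'
#' @param ont An `eq_ontology`.
#' @param edges Optional tibble of relation edges (`subject`,
#'   `predicate`, `object`), e.g. from [materialize()].
#' @param path Optional output file.
#' @return JSON text (invisibly when written to `path`).
#' @export
write_obograph_json <- function(ont, edges = NULL, path = NULL) {
  expand <- function(id) {
    if (id == TOP) return("http://www.w3.org/2002/07/owl#Thing")
    tryCatch(expand_curie(id, ont$prefixes), error = function(e) id)
  }
  nodes <- lapply(sort(names(ont$terms)), function(id) {
    t <- ont$terms[[id]]
    n <- list(id = expand(id), lbl = t$label %||% NA_character_, type = "CLASS")
    if (is.na(n$lbl)) n$lbl <- NULL
    if (t$deprecated) n$meta <- list(deprecated = TRUE)
    n
  })
  edge_list <- list()
  if (!is.null(edges) && nrow(edges)) {
    edges <- edges[do.call(order, edges[c("subject", "predicate", "object")]), ]
    edge_list <- lapply(seq_len(nrow(edges)), function(i) {
      list(
        sub = expand(edges$subject[i]),
        pred = if (edges$predicate[i] == "is_a") "is_a" else expand(edges$predicate[i]),
        obj = expand(edges$object[i])
      )
    })
  }
  doc <- list(nodes = nodes, edges = edge_list)
  text <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(as.character(text)))
  }
  as.character(text)
}
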