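# Manchester-like mini syntax for EL class expressions, used by pattern
# logic schemas and the `query` CLI subcommand:
#   expr    := atom ("and" atom)*
#   atom    := "(" expr ")" | CURIE | CURIE "some" atom
# Constructs outside the EL fragment ("or", "not", "only", "value",
# cardinalities) are rejected with a clear error.

#' Parse a Manchester-like EL class expression
#'
#' @param text Expression string, e.g.
#'   `"PATO:0000070 and (RO:0000052 some CHEBI:25094)"`.
#' @return An `eq_expr`.
#' @export
#' @examples
#' parse_class_expression("PATO:0000051 and (RO:0002314 some UBERON:0004535)")
parse_class_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  bad <- c("or", "not", "only", "value", "min", "max", "exactly", "Self")

  parse_atom <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of expression in '", text, "'", call. = FALSE)
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")")) {
        stop("expected ')' at token ", pos - 1L, " in '", text, "'", call. = FALSE)
      }
      return(e)
    }
    if (t %in% bad) {
      stop("construct '", t, "' is outside the supported EL fragment: '",
           text, "'", call. = FALSE)
    }
    if (t == ")") stop("unexpected ')' in '", text, "'", call. = FALSE)
    if (identical(peek(), "some")) {
      take()
      return(c_some(t, parse_atom()))
    }
    c_named(t)
  }

  parse_expr <- function() {
    ops <- list(parse_atom())
    while (identical(peek(), "and")) {
      take()
      ops <- c(ops, list(parse_atom()))
    }
    if (!is.na(peek()) && peek() %in% bad) {
      stop("construct '", peek(), "' is outside the supported EL fragment: '",
           text, "'", call. = FALSE)
    }
    if (length(ops) == 1L) ops[[1]] else c_and(ops)
  }

  e <- parse_expr()
  if (!is.na(peek())) {
    stop("trailing tokens starting at '", peek(), "' in '", text, "'", call. = FALSE)
  }
  canonicalize(e)
}
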