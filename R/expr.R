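# Class expressions: named classes, existential restrictions ("R some Y")
# and conjunctions over them.  CURIE strings are the universal token
# currency of the package: the same identifier keys corpus tokens, graph
# nodes and embedding rows.

CURIE_RE <- "^[A-Za-z][A-Za-z0-9_]*:[A-Za-z0-9_]+$"
IDENT_RE <- "^[A-Za-z][A-Za-z0-9_]*$"

#' Test whether strings are compact class identifiers (CURIEs)
#'
#' A CURIE is `PREFIX:LOCALID` where the prefix starts with a letter and
#' both parts are alphanumeric/underscore, e.g. `GO:0019556` or
#' `CHEBI:16397`.
#'
#' @param x Character vector.
#' @return Logical vector.
#' @export
is_curie <- function(x) grepl(CURIE_RE, x)

is_ident <- function(x) grepl(IDENT_RE, x)

#' Prefix (ID space) of a CURIE
#'
#' @param x Character vector of CURIEs.
#' @return Character vector of prefixes, e.g. `"GO"` for `"GO:0019556"`.
#' @export
curie_prefix <- function(x) sub(":.*$", "", x)

#' Construct class expressions
#'
#' Class expressions are the object side of axioms: a named class, an
#' existential restriction `R some <expr>`, or a conjunction of two or
#' more expressions.  Conjunctions are flattened and their conjuncts
#' sorted lexicographically by serialization, so structurally equal
#' expressions have identical canonical forms.
#'
#' @param id A CURIE naming a class.
#' @param rel Relation identifier (CURIE or bare identifier such as
#'   `part_of`).
#' @param filler A `ClassExpr` (or a CURIE, promoted to a named class).
#' @param args List of at least two `ClassExpr` (or CURIE) conjuncts.
#' @return A `ClassExpr` object.
#' @examples
#' ce_some("has_participant", ce_class("CHEBI:16397"))
#' @export
ce_class <- function(id) {
  if (!(is.character(id) && length(id) == 1L && is_curie(id))) {
    stop("named class must be a single CURIE, got: ", paste(id, collapse = " "))
  }
  structure(list(type = "class", id = id), class = "ClassExpr")
}

#' @rdname ce_class
#' @export
ce_some <- function(rel, filler) {
  if (!(is.character(rel) && length(rel) == 1L && (is_curie(rel) || is_ident(rel)))) {
    stop("relation must be a CURIE or bare identifier, got: ",
         paste(rel, collapse = " "))
  }
  if (is.character(filler)) filler <- ce_class(filler)
  stopifnot(inherits(filler, "ClassExpr"))
  structure(list(type = "some", rel = rel, filler = filler), class = "ClassExpr")
}

#' @rdname ce_class
#' @export
ce_and <- function(args) {
  args <- lapply(args, function(a) if (is.character(a)) ce_class(a) else a)
  flat <- list()
  for (a in args) {
    stopifnot(inherits(a, "ClassExpr"))
    flat <- if (a$type == "and") c(flat, a$args) else c(flat, list(a))
  }
  if (length(flat) < 2L) stop("conjunction needs at least 2 conjuncts")
  flat <- flat[order(vapply(flat, expr_string, character(1)), method = "radix")]
  structure(list(type = "and", args = flat), class = "ClassExpr")
}

#' Canonical serialization of a class expression
#'
#' `expr_string()` renders the unambiguous form used for axiom identity
#' and for the axiom-lines file format (`some` binds tighter than `and`;
#' conjunction fillers are parenthesized).  `expr_tokens()` renders the
#' flat, parenthesis-free token sequence used in corpus sentences.
#'
#' @param e A `ClassExpr`.
#' @return A string (`expr_string`) or character vector of tokens
#'   (`expr_tokens`).
#' @export
expr_string <- function(e) {
  switch(e$type,
    class = e$id,
    some = {
      f <- expr_string(e$filler)
      if (e$filler$type == "and") f <- paste0("( ", f, " )")
      paste(e$rel, "some", f)
    },
    and = paste(vapply(e$args, function(a) {
      s <- expr_string(a)
      if (a$type == "and") paste0("( ", s, " )") else s
    }, character(1)), collapse = " and "),
    stop("unknown expression type: ", e$type)
  )
}

#' @rdname expr_string
#' @export
expr_tokens <- function(e) {
  switch(e$type,
    class = e$id,
    some = c(e$rel, "some", expr_tokens(e$filler)),
    and = {
      out <- expr_tokens(e$args[[1L]])
      for (a in e$args[-1L]) out <- c(out, "and", expr_tokens(a))
      out
    },
    stop("unknown expression type: ", e$type)
  )
}

#' Named classes mentioned in a class expression
#'
#' @param e A `ClassExpr`.
#' @return Character vector of distinct CURIEs (relations excluded).
#' @export
expr_classes <- function(e) {
  switch(e$type,
    class = e$id,
    some = expr_classes(e$filler),
    and = unique(unlist(lapply(e$args, expr_classes), use.names = FALSE))
  )
}

#' @export
print.ClassExpr <- function(x, ...) {
  cat("<ClassExpr> ", expr_string(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.ClassExpr <- function(x, ...) expr_string(x)

# --- recursive-descent parser over whitespace tokens --------------------
#
# EXPR := CONJ
# CONJ := PRIM ("and" PRIM)*
# PRIM := CURIE | REL "some" PRIM | "(" EXPR ")"

tokenize_expr_text <- function(text) {
  text <- gsub("(", " ( ", text, fixed = TRUE)
  text <- gsub(")", " ) ", text, fixed = TRUE)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1L]]
  toks[nzchar(toks)]
}

parse_expr_tokens <- function(toks, where = "expression") {
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  st$where <- where
  e <- p_conj(st)
  if (st$i <= length(st$toks)) {
    stop("trailing tokens after ", where, ": ",
         paste(st$toks[st$i:length(st$toks)], collapse = " "))
  }
  e
}

parse_expr_string <- function(text, where = "expression") {
  parse_expr_tokens(tokenize_expr_text(text), where = where)
}

p_peek <- function(st) if (st$i <= length(st$toks)) st$toks[[st$i]] else NA_character_

p_take <- function(st) {
  if (st$i > length(st$toks)) stop("unexpected end of ", st$where)
  tok <- st$toks[[st$i]]
  st$i <- st$i + 1L
  tok
}

p_conj <- function(st) {
  items <- list(p_prim(st))
  while (identical(p_peek(st), "and")) {
    p_take(st)
    items <- c(items, list(p_prim(st)))
  }
  if (length(items) == 1L) items[[1L]] else ce_and(items)
}

p_prim <- function(st) {
  tok <- p_take(st)
  if (tok == "(") {
    e <- p_conj(st)
    closing <- p_take(st)
    if (closing != ")") stop("expected ')' in ", st$where, ", got: ", closing)
    return(e)
  }
  if (identical(p_peek(st), "some")) {
    p_take(st)
    return(ce_some(tok, p_prim(st)))
  }
  if (!is_curie(tok)) stop("expected a class CURIE in ", st$where, ", got: ", tok)
  ce_class(tok)
}
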