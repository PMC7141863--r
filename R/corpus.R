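# Sentence corpora for skip-gram training: logical-axiom sentences and
# annotation sentences (optionally class meta-data sentences and
# user-supplied background text).  Corpora are pure functions of their
# inputs: construction is deterministic and bit-identical across runs.

#' Construct a corpus
#'
#' A corpus is an ordered list of sentences, each a character vector of
#' tokens.  Empty sentences are rejected.
#'
#' @param sentences List of non-empty character vectors.
#' @return A `Corpus` object.
#' @export
corpus <- function(sentences = list()) {
  stopifnot(is.list(sentences))
  if (length(sentences) &&
      any(vapply(sentences, length, integer(1)) == 0L)) {
    stop("corpus sentences must be non-empty")
  }
  structure(sentences, class = "Corpus")
}

#' @export
print.Corpus <- function(x, ...) {
  cat("<Corpus> ", length(x), " sentences, ",
      length(unique(unlist(x, use.names = FALSE))), " distinct tokens\n",
      sep = "")
  invisible(x)
}

#' Concatenate corpora
#'
#' @param ... `Corpus` objects.
#' @return A single `Corpus` with the sentences in argument order.
#' @export
corpus_append <- function(...) {
  parts <- list(...)
  corpus(do.call(c, lapply(parts, unclass)))
}

#' Read and write corpora as plain text
#'
#' One sentence per line, space-separated tokens.
#'
#' @param x A `Corpus`.
#' @param path File path.
#' @return `write_corpus` returns `path` invisibly; `read_corpus`
#'   returns a `Corpus`.
#' @export
write_corpus <- function(x, path) {
  writeLines(vapply(x, paste, character(1), collapse = " "), path)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  corpus(strsplit(trimws(lines), "[[:space:]]+"))
}

#' Read entity-class annotation assertions
#'
#' Supports a simple headerless TSV with columns (entity, class[,
#' evidence]) and the GAF 2.x format (comment lines starting with `!`
#' skipped; column 2 = entity, column 5 = class, column 7 = evidence
#' code).  Assertions whose evidence code is in `excluded_evidence` are
#' dropped — e.g. `excluded_evidence = "IEA"` removes electronically
#' inferred annotations.  Entity identifiers must not contain `:`
#' (unless carrying the reserved `ENT:` prefix) so that entity and
#' class tokens occupy disjoint spaces.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"gaf"`.
#' @param excluded_evidence Character vector of evidence codes to drop.
#' @return Data frame with columns `entity`, `class`, `evidence`
#'   (possibly `NA`), deduplicated and canonically ordered.
#' @export
read_annotations <- function(path, dialect = c("tsv", "gaf"),
                             excluded_evidence = character()) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "!")
  rows <- strsplit(lines, "\t", fixed = TRUE)
  ent <- cls <- ev <- character(0)
  for (ln in which(keep)) {
    f <- rows[[ln]]
    if (dialect == "tsv") {
      if (length(f) < 2L || !nzchar(trimws(f[[1L]])) || !nzchar(trimws(f[[2L]]))) {
        stop("missing entity/class on line ", ln, " of ", path)
      }
      e <- trimws(f[[1L]]); k <- trimws(f[[2L]])
      v <- if (length(f) >= 3L && nzchar(trimws(f[[3L]]))) trimws(f[[3L]]) else NA_character_
    } else {
      if (length(f) < 7L || !nzchar(trimws(f[[2L]])) || !nzchar(trimws(f[[5L]]))) {
        stop("missing entity/class on line ", ln, " of ", path)
      }
      e <- trimws(f[[2L]]); k <- trimws(f[[5L]])
      v <- if (nzchar(trimws(f[[7L]]))) trimws(f[[7L]]) else NA_character_
    }
    ent <- c(ent, e); cls <- c(cls, k); ev <- c(ev, v)
  }
  bad <- grepl(":", ent, fixed = TRUE) & !startsWith(ent, "ENT:")
  if (any(bad)) {
    stop("entity identifiers may not contain ':' (reserve the ENT: prefix): ",
         paste(utils::head(unique(ent[bad]), 3L), collapse = ", "))
  }
  if (!all(is_curie(cls))) {
    stop("annotation classes must be CURIEs: ",
         paste(utils::head(unique(cls[!is_curie(cls)]), 3L), collapse = ", "))
  }
  df <- data.frame(entity = ent, class = cls, evidence = ev,
                   stringsAsFactors = FALSE)
  df <- df[!(df$evidence %in% excluded_evidence), , drop = FALSE]
  df <- unique(df)
  df <- df[order(df$entity, df$class, df$evidence, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build the logical-axiom + annotation sentence corpus
#'
#' One sentence per axiom — its flat token serialization `(subject,
#' kind, object tokens with some/and keywords)` — followed by one
#' sentence `(entity, annotation_relation, class)` per annotation
#' assertion.  Axiom sentences come in canonical axiom order,
#' annotation sentences in lexicographic order; the result is therefore
#' a deterministic function of its inputs.  Feed a saturated ontology
#' to include inferred axioms in the corpus.
#'
#' @param o An `OntologySet`, typically [saturate()]d.
#' @param ann Annotation data frame (see [read_annotations()]), or
#'   `NULL`.
#' @param annotation_relation Token linking entity and class sentences.
#' @return A `Corpus`.
#' @export
build_logical_corpus <- function(o, ann = NULL,
                                 annotation_relation = "hasAssociation") {
  ax <- o$axioms
  sent <- lapply(seq_len(nrow(ax)), function(i) {
    c(ax$subject[[i]], ax$kind[[i]], expr_tokens(ax$object[[i]]))
  })
  if (!is.null(ann) && nrow(ann)) {
    pairs <- unique(ann[c("entity", "class")])
    pairs <- pairs[order(pairs$entity, pairs$class, method = "radix"), ,
                   drop = FALSE]
    sent <- c(sent, lapply(seq_len(nrow(pairs)), function(i) {
      c(pairs$entity[[i]], annotation_relation, pairs$class[[i]])
    }))
  }
  corpus(sent)
}

#' Tokenize meta-data text
#'
#' Lowercases and splits on whitespace and the punctuation set
#' `.,;()[]{}"`.  Colons are deliberately not separators, so CURIEs and
#' formula-like tokens survive intact.
#'
#' @param text Character vector.
#' @return List of token vectors (one per input string).
#' @export
tokenize_text <- function(text) {
  text <- tolower(text)
  text <- gsub('[].,;(){}"[]', " ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")
  lapply(toks, function(t) t[nzchar(t)])
}

#' Build the meta-data sentence corpus
#'
#' One sentence per selected metadata assertion: the subject CURIE, the
#' property keyword, then the tokenized text.  Assertions with no
#' surviving text tokens are dropped.
#'
#' @param o An `OntologySet`.
#' @param properties Subset of `label`, `synonym`, `definition`,
#'   `comment` to include.
#' @return A `Corpus` (empty when `properties` is empty).
#' @export
build_metadata_corpus <- function(o,
                                  properties = c("label", "synonym",
                                                 "definition")) {
  stopifnot(all(properties %in% METADATA_PROPERTIES))
  md <- o$metadata[o$metadata$property %in% properties, , drop = FALSE]
  if (!nrow(md)) return(corpus())
  md <- md[order(md$subject, md$property, md$text, method = "radix"), ,
           drop = FALSE]
  toks <- tokenize_text(md$text)
  sent <- lapply(seq_len(nrow(md)), function(i) {
    c(md$subject[[i]], md$property[[i]], toks[[i]])
  })
  corpus(sent[vapply(sent, length, integer(1)) > 2L])
}

#' Read a plain-text background corpus
#'
#' Background text (e.g. literature abstracts) supplied by the user is
#' tokenized line-by-line with [tokenize_text()] and can be appended to
#' an ontology corpus with [corpus_append()], or used to warm-start
#' training via the `init` argument of [train_embeddings()] for a
#' two-phase (pre-train, then continue) regime.
#'
#' @param path File path of plain text, one sentence per line.
#' @return A `Corpus`.
#' @export
read_background_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- tokenize_text(lines)
  corpus(toks[vapply(toks, length, integer(1)) > 0L])
}
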