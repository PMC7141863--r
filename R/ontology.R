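# Ontology sets: deduplicated collections of logical axioms plus class
# meta-data, with CURIE-prefix bookkeeping.  This is the data backbone
# every other stage (saturation, corpora, graphs, ablations) consumes.

AXIOM_KINDS <- c("SubClassOf", "EquivalentTo", "DisjointWith")
METADATA_PROPERTIES <- c("label", "synonym", "definition", "comment")

#' Construct a single logical axiom
#'
#' Axioms relate a named subject class to a class expression via
#' `SubClassOf`, `EquivalentTo` or `DisjointWith`.  `DisjointWith`
#' objects must be named classes.  The identity of an axiom is the
#' triple (subject, kind, canonical object serialization); origin and
#' source are provenance only and do not distinguish axioms.
#'
#' @param kind One of `"SubClassOf"`, `"EquivalentTo"`, `"DisjointWith"`.
#' @param subject CURIE of the subject class.
#' @param object A `ClassExpr`, or a CURIE promoted to a named class.
#' @param origin `"asserted"` or `"inferred"`.
#' @param source Free-text ontology tag (e.g. a filename stem).
#' @return An `Axiom` object.
#' @export
axiom <- function(kind, subject, object, origin = "asserted", source = "") {
  kind <- match.arg(kind, AXIOM_KINDS)
  origin <- match.arg(origin, c("asserted", "inferred"))
  if (!(is.character(subject) && length(subject) == 1L && is_curie(subject))) {
    stop("axiom subject must be a named class CURIE, got: ",
         paste(subject, collapse = " "))
  }
  if (is.character(object)) object <- ce_class(object)
  stopifnot(inherits(object, "ClassExpr"))
  if (kind == "DisjointWith" && object$type != "class") {
    stop("DisjointWith object must be a named class")
  }
  structure(list(kind = kind, subject = subject, object = object,
                 origin = origin, source = source),
            class = "Axiom")
}

#' @export
print.Axiom <- function(x, ...) {
  cat("<Axiom [", x$origin, "] ", x$subject, " ", x$kind, " ",
      expr_string(x$object), ">\n", sep = "")
  invisible(x)
}

empty_axiom_df <- function() {
  df <- data.frame(kind = character(), subject = character(),
                   obj = character(), origin = character(),
                   source = character(), stringsAsFactors = FALSE)
  df$object <- I(list())
  df
}

axiom_df <- function(axioms) {
  if (length(axioms) == 0L) return(empty_axiom_df())
  df <- data.frame(
    kind = vapply(axioms, `[[`, character(1), "kind"),
    subject = vapply(axioms, `[[`, character(1), "subject"),
    obj = vapply(axioms, function(a) expr_string(a$object), character(1)),
    origin = vapply(axioms, `[[`, character(1), "origin"),
    source = vapply(axioms, `[[`, character(1), "source"),
    stringsAsFactors = FALSE)
  df$object <- I(lapply(axioms, `[[`, "object"))
  canonicalize_axiom_df(df)
}

axiom_keys <- function(df) paste(df$subject, df$kind, df$obj)

# Sort by identity key and deduplicate; asserted provenance wins over
# inferred when both carry the same key.
canonicalize_axiom_df <- function(df) {
  if (!nrow(df)) return(df)
  ord <- order(axiom_keys(df), match(df$origin, c("asserted", "inferred")),
               method = "radix")
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(axiom_keys(df)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_metadata_df <- function() {
  data.frame(subject = character(), property = character(),
             text = character(), stringsAsFactors = FALSE)
}

canonicalize_metadata_df <- function(df) {
  if (!nrow(df)) return(empty_metadata_df())
  stopifnot(all(df$property %in% METADATA_PROPERTIES))
  if (any(!nzchar(df$text))) stop("metadata text must be non-empty")
  df <- unique(df[c("subject", "property", "text")])
  df <- df[order(df$subject, df$property, df$text, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Construct an ontology set
#'
#' An `OntologySet` bundles a deduplicated set of axioms, a set of class
#' meta-data assertions (labels, synonyms, definitions, comments) and
#' the registry of CURIE prefixes mentioned by the axioms.  Axioms are
#' kept in canonical order (sorted by identity key), so two sets built
#' from the same axioms in any order are `identical()`.
#'
#' @param axioms A list of [axiom()] objects, or an axiom data frame.
#' @param metadata Data frame with columns `subject`, `property`,
#'   `text`.
#' @param prefixes Extra prefixes to register beyond those mentioned.
#' @return An `OntologySet`.
#' @export
ontology_set <- function(axioms = list(), metadata = empty_metadata_df(),
                         prefixes = character()) {
  ax <- if (is.data.frame(axioms)) canonicalize_axiom_df(axioms) else axiom_df(axioms)
  md <- canonicalize_metadata_df(metadata)
  mentioned <- unlist(lapply(seq_len(nrow(ax)), function(i) {
    c(ax$subject[[i]], expr_classes(ax$object[[i]]))
  }), use.names = FALSE)
  pref <- sort(unique(c(prefixes, curie_prefix(unique(mentioned)))))
  structure(list(axioms = ax, metadata = md, prefixes = pref),
            class = "OntologySet")
}

#' Number of axioms in an ontology set
#' @param o An `OntologySet`.
#' @return Integer count.
#' @export
n_axioms <- function(o) nrow(o$axioms)

#' @export
print.OntologySet <- function(x, ...) {
  cat("<OntologySet> ", nrow(x$axioms), " axioms (",
      sum(x$axioms$origin == "inferred"), " inferred), ",
      nrow(x$metadata), " metadata assertions, prefixes: ",
      paste(x$prefixes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Per-axiom sets of mentioned named classes / prefixes.
axiom_mentions <- function(o) {
  lapply(seq_len(nrow(o$axioms)), function(i) {
    unique(c(o$axioms$subject[[i]], expr_classes(o$axioms$object[[i]])))
  })
}

axiom_mention_prefixes <- function(o) {
  lapply(axiom_mentions(o), function(m) unique(curie_prefix(m)))
}

#' Parse-report of an ontology set
#'
#' Returns the parse report attached by [parse_ontology()]: counts of
#' axioms and metadata read plus any skipped constructs (with reasons).
#'
#' @param o An `OntologySet`.
#' @return A list with elements `n_axioms`, `n_metadata`, `skipped`.
#' @export
parse_report <- function(o) {
  rep <- attr(o, "report")
  if (is.null(rep)) {
    rep <- list(n_axioms = n_axioms(o), n_metadata = nrow(o$metadata),
                skipped = character())
  }
  rep
}

# ---------------------------------------------------------------------
# Parsing

#' Read an ontology from a file
#'
#' Two dialects are supported.  The `axiom-lines` format carries one
#' axiom per line, whitespace-tokenized:
#' `SUBJ (SubClassOf|EquivalentTo|DisjointWith) EXPR` with
#' `EXPR := CURIE | REL some EXPR | EXPR and EXPR` (optional
#' parentheses; `some` binds tighter than `and`).  The `obo` dialect
#' reads OBO 1.4 `[Term]` stanzas and maps `is_a` to a named
#' `SubClassOf`, `relationship: R Y` to `SubClassOf (R some Y)`, the
#' `intersection_of` set to an `EquivalentTo` conjunction,
#' `disjoint_from` to `DisjointWith`, and `name`/`synonym`/`def`/
#' `comment` to metadata assertions.  Constructs outside this fragment
#' (e.g. `union_of`) are skipped with a warning and recorded in the
#' parse report.
#'
#' @param path File path.
#' @param format `"obo"` or `"axiom-lines"`.
#' @param source Ontology tag recorded on every axiom; defaults to the
#'   filename stem.
#' @return An `OntologySet` with all axioms `origin = "asserted"`.
#' @examples
#' f <- tempfile(fileext = ".axioms")
#' writeLines("GO:0019556 SubClassOf has_participant some CHEBI:16397", f)
#' o <- parse_ontology(f, format = "axiom-lines")
#' n_axioms(o)
#' @export
parse_ontology <- function(path, format = c("obo", "axiom-lines"),
                           source = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(source)) source <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  if (format == "axiom-lines") {
    parse_axiom_lines(lines, source)
  } else {
    parse_obo_lines(lines, source)
  }
}

parse_axiom_lines <- function(lines, source) {
  axs <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line) || startsWith(line, "#")) next
    toks <- tokenize_expr_text(line)
    if (length(toks) < 3L) {
      stop("malformed axiom on line ", ln, ": ", line)
    }
    subject <- toks[[1L]]
    kind <- toks[[2L]]
    if (!is_curie(subject) || !(kind %in% AXIOM_KINDS)) {
      stop("malformed axiom on line ", ln, ": ", line)
    }
    axs[[length(axs) + 1L]] <- tryCatch({
      object <- parse_expr_tokens(toks[-(1:2)], where = paste0("line ", ln))
      axiom(kind, subject, object, source = source)
    }, error = function(e) stop("malformed axiom on line ", ln, ": ",
                                conditionMessage(e), call. = FALSE))
  }
  o <- ontology_set(axs)
  attr(o, "report") <- list(n_axioms = n_axioms(o), n_metadata = 0L,
                            skipped = character())
  o
}

obo_strip_comment <- function(value) trimws(sub("\\s!.*$", "", value))

obo_quoted <- function(value, ln) {
  m <- regmatches(value, regexpr('"(\\\\.|[^"\\\\])*"', value))
  if (length(m) == 0L) stop("expected quoted text on line ", ln, ": ", value)
  txt <- substr(m, 2L, nchar(m) - 1L)
  gsub('\\\\(["\\\\])', "\\1", txt)
}

parse_obo_lines <- function(lines, source) {
  axs <- list()
  md <- list()
  skipped <- character()
  in_term <- FALSE
  cur <- NULL
  cur_line <- 0L

  flush_term <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id)) {
      stop("malformed [Term] stanza at line ", cur_line, ": missing id")
    }
    if (length(cur$intersection) >= 1L) {
      conj <- lapply(cur$intersection, function(p) {
        if (length(p) == 1L) ce_class(p) else ce_some(p[[1L]], p[[2L]])
      })
      obj <- if (length(conj) == 1L) conj[[1L]] else ce_and(conj)
      axs[[length(axs) + 1L]] <<- axiom("EquivalentTo", cur$id, obj,
                                        source = source)
    }
    for (a in cur$axioms) {
      axs[[length(axs) + 1L]] <<- axiom(a$kind, cur$id, a$object,
                                        source = source)
    }
    for (m in cur$metadata) {
      md[[length(md) + 1L]] <<- list(subject = cur$id,
                                     property = m$property, text = m$text)
    }
  }

  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line)) next
    if (startsWith(line, "[")) {
      flush_term()
      cur <- NULL
      in_term <- identical(line, "[Term]")
      if (in_term) {
        cur <- list(id = NULL, intersection = list(), axioms = list(),
                    metadata = list())
        cur_line <- ln
      }
      next
    }
    if (!in_term) next  # header or [Typedef] body
    sep <- regexpr(":", line, fixed = TRUE)
    if (sep < 0L) stop("malformed line ", ln, ": ", line)
    tag <- substr(line, 1L, sep - 1L)
    value <- trimws(substr(line, sep + 1L, nchar(line)))
    switch(tag,
      id = {
        value <- obo_strip_comment(value)
        if (!is_curie(value)) stop("malformed id on line ", ln, ": ", value)
        cur$id <- value
      },
      name = {
        cur$metadata[[length(cur$metadata) + 1L]] <-
          list(property = "label", text = value)
      },
      comment = {
        cur$metadata[[length(cur$metadata) + 1L]] <-
          list(property = "comment", text = value)
      },
      synonym = {
        cur$metadata[[length(cur$metadata) + 1L]] <-
          list(property = "synonym", text = obo_quoted(value, ln))
      },
      def = {
        cur$metadata[[length(cur$metadata) + 1L]] <-
          list(property = "definition", text = obo_quoted(value, ln))
      },
      is_a = {
        value <- obo_strip_comment(value)
        if (!is_curie(value)) stop("malformed is_a on line ", ln, ": ", value)
        cur$axioms[[length(cur$axioms) + 1L]] <-
          list(kind = "SubClassOf", object = ce_class(value))
      },
      relationship = {
        parts <- strsplit(obo_strip_comment(value), "[[:space:]]+")[[1L]]
        if (length(parts) != 2L) {
          stop("malformed relationship on line ", ln, ": ", value)
        }
        cur$axioms[[length(cur$axioms) + 1L]] <-
          list(kind = "SubClassOf", object = ce_some(parts[[1L]], parts[[2L]]))
      },
      intersection_of = {
        parts <- strsplit(obo_strip_comment(value), "[[:space:]]+")[[1L]]
        if (!(length(parts) %in% 1:2)) {
          stop("malformed intersection_of on line ", ln, ": ", value)
        }
        cur$intersection[[length(cur$intersection) + 1L]] <- parts
      },
      disjoint_from = {
        value <- obo_strip_comment(value)
        if (!is_curie(value)) {
          stop("malformed disjoint_from on line ", ln, ": ", value)
        }
        cur$axioms[[length(cur$axioms) + 1L]] <-
          list(kind = "DisjointWith", object = ce_class(value))
      },
      union_of = ,
      equivalent_to = {
        skipped <- c(skipped,
                     sprintf("line %d: unsupported construct '%s'", ln, tag))
      },
      NULL  # other tags (namespace, xref, alt_id, ...) are ignored
    )
  }
  flush_term()

  o <- ontology_set(axs,
                    metadata = if (length(md)) {
                      data.frame(subject = vapply(md, `[[`, character(1), "subject"),
                                 property = vapply(md, `[[`, character(1), "property"),
                                 text = vapply(md, `[[`, character(1), "text"),
                                 stringsAsFactors = FALSE)
                    } else empty_metadata_df())
  if (length(skipped)) {
    warning("skipped ", length(skipped), " unsupported OBO construct(s)")
  }
  attr(o, "report") <- list(n_axioms = n_axioms(o), n_metadata = nrow(o$metadata),
                            skipped = skipped)
  o
}
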