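# Writing ontologies back to disk, and the two set-level operations the
# ablation harness is built from: namespace-restricted filtering of
# cross-ontology axioms, and merge/substitution of whole axiom sets.

#' Write an ontology to a file
#'
#' The `axiom-lines` writer emits one canonical axiom serialization per
#' line (metadata is not representable in this format and is omitted).
#' The `obo` writer emits one `[Term]` stanza per subject class with the
#' supported tags (`name`, `def`, `comment`, `synonym`, `is_a`,
#' `relationship`, `intersection_of`, `disjoint_from`).  Axioms that the
#' OBO fragment cannot express (e.g. a `SubClassOf` whose object is a
#' conjunction) are skipped with a warning.  Re-parsing a writer's
#' output reproduces the expressible subset exactly.
#'
#' @param o An `OntologySet`.
#' @param path Output file path.
#' @param format `"obo"` or `"axiom-lines"`.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(o, path, format = c("obo", "axiom-lines")) {
  format <- match.arg(format)
  lines <- if (format == "axiom-lines") {
    ax <- o$axioms
    paste(ax$subject, ax$kind, ax$obj)
  } else {
    obo_render(o)
  }
  writeLines(lines, path)
  invisible(path)
}

obo_expressible <- function(kind, object) {
  if (kind == "DisjointWith") return(TRUE)
  if (kind == "SubClassOf") {
    return(object$type == "class" ||
           (object$type == "some" && object$filler$type == "class"))
  }
  # EquivalentTo: intersection_of of named classes / simple existentials
  conj <- if (object$type == "and") object$args else list(object)
  all(vapply(conj, function(c) {
    c$type == "class" || (c$type == "some" && c$filler$type == "class")
  }, logical(1)))
}

obo_render <- function(o) {
  ax <- o$axioms
  md <- o$metadata
  ok <- vapply(seq_len(nrow(ax)), function(i) {
    obo_expressible(ax$kind[[i]], ax$object[[i]])
  }, logical(1))
  if (any(!ok)) {
    warning("skipped ", sum(!ok),
            " axiom(s) not expressible in the OBO fragment")
  }
  ax <- ax[ok, , drop = FALSE]
  subjects <- sort(unique(c(ax$subject, md$subject)))
  out <- c("format-version: 1.4", "")
  for (s in subjects) {
    out <- c(out, "[Term]", paste0("id: ", s))
    mi <- md[md$subject == s, , drop = FALSE]
    for (p in c("label", "definition", "comment", "synonym")) {
      for (txt in mi$text[mi$property == p]) {
        out <- c(out, switch(p,
          label = paste0("name: ", txt),
          definition = sprintf('def: "%s" []', txt),
          comment = paste0("comment: ", txt),
          synonym = sprintf('synonym: "%s" EXACT []', txt)))
      }
    }
    ai <- ax[ax$subject == s, , drop = FALSE]
    for (i in seq_len(nrow(ai))) {
      obj <- ai$object[[i]]
      out <- c(out, switch(ai$kind[[i]],
        SubClassOf = if (obj$type == "class") {
          paste0("is_a: ", obj$id)
        } else {
          sprintf("relationship: %s %s", obj$rel, obj$filler$id)
        },
        DisjointWith = paste0("disjoint_from: ", obj$id),
        EquivalentTo = {
          conj <- if (obj$type == "and") obj$args else list(obj)
          vapply(conj, function(c) {
            if (c$type == "class") paste0("intersection_of: ", c$id)
            else sprintf("intersection_of: %s %s", c$rel, c$filler$id)
          }, character(1))
        }))
    }
    out <- c(out, "")
  }
  out
}

#' Keep base-internal axioms plus links into one external namespace
#'
#' Filters an enriched ontology down to the axioms internal to the base
#' ID space plus exactly those axioms that reference one chosen external
#' ID space: an axiom is kept if and only if the set of prefixes of the
#' named classes it mentions is a subset of `{base_prefix,
#' external_prefix}`.  This isolates the contribution of a single
#' referenced ontology's cross-links.  The output is a subset of the
#' input and the operation is idempotent.  Metadata assertions are kept
#' when their subject carries one of the two prefixes.
#'
#' @param o An `OntologySet`.
#' @param external_prefix The external ID space to retain links to
#'   (e.g. `"CHEBI"`).
#' @param base_prefix The base ontology's ID space (e.g. `"GO"`).
#' @return A filtered `OntologySet`.
#' @export
restrict_to_namespace_links <- function(o, external_prefix, base_prefix) {
  keep_pref <- c(base_prefix, external_prefix)
  men <- axiom_mention_prefixes(o)
  keep <- vapply(men, function(p) all(p %in% keep_pref), logical(1))
  ax <- o$axioms[keep, , drop = FALSE]
  md <- o$metadata[curie_prefix(o$metadata$subject) %in% keep_pref, ,
                   drop = FALSE]
  ontology_set(ax, metadata = md)
}

#' Merge two ontology sets, optionally substituting a sub-ontology
#'
#' Without `replace_prefix` this is a deduplicating union of axioms and
#' metadata (commutative and idempotent).  With `replace_prefix`, every
#' host axiom whose mentioned classes are *all* of that prefix is
#' deleted first (as are metadata assertions on classes of that prefix),
#' then the incoming set is unioned in.  This supports replacing a
#' sub-ontology inside a larger one (e.g. swapping the basic edition of
#' an ontology for its axiom-enriched edition inside a composite
#' phenotype ontology) as well as importing the full axiom set of a
#' referenced external ontology.
#'
#' @param host,incoming `OntologySet` objects.
#' @param replace_prefix Optional CURIE prefix to substitute.
#' @return The merged `OntologySet`.
#' @export
merge_or_substitute <- function(host, incoming, replace_prefix = NULL) {
  ax_host <- host$axioms
  md_host <- host$metadata
  if (!is.null(replace_prefix)) {
    men <- axiom_mention_prefixes(host)
    drop <- vapply(men, function(p) all(p == replace_prefix), logical(1))
    ax_host <- ax_host[!drop, , drop = FALSE]
    md_host <- md_host[curie_prefix(md_host$subject) != replace_prefix, ,
                       drop = FALSE]
  }
  ax <- rbind(ax_host, incoming$axioms)
  md <- rbind(md_host, incoming$metadata)
  ontology_set(ax, metadata = md,
               prefixes = union(host$prefixes, incoming$prefixes))
}
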