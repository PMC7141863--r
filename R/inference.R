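# Structural saturation: an EL-style closure that completes the class
# hierarchy before corpus or graph construction, standing in for the
# inferred axioms a semantic reasoner would add.
#
# Rules (applied to fixpoint):
#   R1  A EquivalentTo E          =>  A SubClassOf c for each conjunct c
#                                     of E; if E is a named class B,
#                                     also B SubClassOf A.
#   R2  A SubClassOf B, B SubClassOf C (named)  =>  A SubClassOf C.
#   R3  A SubClassOf R some B, B SubClassOf C (named)
#                                 =>  A SubClassOf R some C.
#
# The fragment terminates without deepening expressions: R2 is bounded
# by the named-class vocabulary and R3 only swaps a named filler for a
# named superclass.  Cycles are permitted; classes on a cycle become
# mutual (and self-) subclasses.  Disjointness passes through untouched.

# All (A, B) with a directed path of length >= 1 in the named-subclass
# relation (so asserted pairs are included, and cycles yield self-pairs).
subclass_closure <- function(a, b) {
  nodes <- unique(c(a, b))
  n <- length(nodes)
  ai <- match(a, nodes)
  bi <- match(b, nodes)
  succ <- vector("list", n)
  for (k in seq_along(ai)) {
    succ[[ai[k]]] <- c(succ[[ai[k]]], bi[k])
  }
  succ <- lapply(succ, unique)
  out_a <- integer(0)
  out_b <- integer(0)
  for (s in seq_len(n)) {
    seen <- logical(n)
    stack <- succ[[s]]
    reach <- integer(0)
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      reach <- c(reach, v)
      stack <- c(stack, succ[[v]][!seen[succ[[v]]]])
    }
    out_a <- c(out_a, rep.int(s, length(reach)))
    out_b <- c(out_b, reach)
  }
  data.frame(a = nodes[out_a], b = nodes[out_b], stringsAsFactors = FALSE)
}

#' Saturate an ontology set
#'
#' Adds inferred axioms (marked `origin = "inferred"`) by expanding
#' equivalences into subclass conjuncts, closing the named-class
#' hierarchy under transitivity, and lifting existential fillers along
#' that hierarchy.  The result is a superset of the input and the
#' operation is monotone and idempotent: `saturate(saturate(o))`
#' equals `saturate(o)`.
#'
#' @param o An `OntologySet`.
#' @return The saturated `OntologySet`.
#' @examples
#' o <- ontology_set(list(
#'   axiom("SubClassOf", "A:1", "A:2"),
#'   axiom("SubClassOf", "A:2", "A:3")))
#' n_axioms(saturate(o))  # transitivity adds A:1 SubClassOf A:3
#' @export
saturate <- function(o) {
  ax <- o$axioms
  if (!nrow(ax)) return(o)
  srcs <- unique(ax$source)
  inf_source <- if (length(srcs) == 1L) srcs else "mixed"

  new_axioms <- list()
  add <- function(subject, object) {
    new_axioms[[length(new_axioms) + 1L]] <<-
      axiom("SubClassOf", subject, object, origin = "inferred",
            source = inf_source)
  }

  # R1: equivalence expansion
  eq_idx <- which(ax$kind == "EquivalentTo")
  for (i in eq_idx) {
    obj <- ax$object[[i]]
    conj <- if (obj$type == "and") obj$args else list(obj)
    for (c in conj) add(ax$subject[[i]], c)
    if (obj$type == "class") add(obj$id, ce_class(ax$subject[[i]]))
  }

  # pool of subclass axioms feeding R2/R3: asserted + R1 output
  pool_subj <- character(0)
  pool_obj <- list()
  sub_idx <- which(ax$kind == "SubClassOf")
  for (i in sub_idx) {
    pool_subj <- c(pool_subj, ax$subject[[i]])
    pool_obj <- c(pool_obj, list(ax$object[[i]]))
  }
  for (a in new_axioms) {
    pool_subj <- c(pool_subj, a$subject)
    pool_obj <- c(pool_obj, list(a$object))
  }

  named <- vapply(pool_obj, function(e) e$type == "class", logical(1))
  if (any(named)) {
    pairs <- subclass_closure(pool_subj[named],
                              vapply(pool_obj[named], `[[`, character(1), "id"))
    sup_of <- split(pairs$b, pairs$a)
    for (k in seq_len(nrow(pairs))) {        # R2 (includes asserted pairs;
      add(pairs$a[[k]], ce_class(pairs$b[[k]]))  # dedup keeps asserted copy)
    }
    # R3: lift named existential fillers along the closed hierarchy
    ex <- which(vapply(pool_obj, function(e) {
      e$type == "some" && e$filler$type == "class"
    }, logical(1)))
    for (i in ex) {
      sups <- sup_of[[pool_obj[[i]]$filler$id]]
      for (s in sups) add(pool_subj[[i]], ce_some(pool_obj[[i]]$rel, s))
    }
  }

  out <- ontology_set(c(df_to_axiom_list(ax), new_axioms),
                      metadata = o$metadata, prefixes = o$prefixes)
  attr(out, "report") <- attr(o, "report")
  out
}

df_to_axiom_list <- function(ax) {
  lapply(seq_len(nrow(ax)), function(i) {
    axiom(ax$kind[[i]], ax$subject[[i]], ax$object[[i]],
          origin = ax$origin[[i]], source = ax$source[[i]])
  })
}
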