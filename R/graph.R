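# Relational-pattern graph: compiles two-class axioms and annotation
# assertions into a labeled graph, then emits second-order biased
# random-walk sentences in the Node2Vec style.

#' Compile axioms and annotations into a relational-pattern graph
#'
#' Edges are produced only by axioms mentioning exactly two named
#' classes, following the pattern rules: `X SubClassOf Y` (named) gives
#' a directed `subClassOf` edge; `X SubClassOf R some Y` gives a
#' directed edge labeled `R`; `X EquivalentTo Y` and
#' `X EquivalentTo R some Y` give the corresponding edge in both
#' directions; `X DisjointWith Y` gives a directed `disjointWith` edge.
#' Each annotation `(e, C)` gives an edge from the entity to the class
#' labeled by `annotation_relation`.  Axioms that mention any other
#' number of named classes, or whose object does not match these
#' patterns, contribute no edge.  Nodes comprise every named class
#' mentioned in the ontology plus every annotated entity, so classes
#' without matching axioms still appear (as isolated nodes).
#'
#' @param o An `OntologySet`, typically [saturate()]d so that
#'   genus-differentia equivalences have been decomposed into two-class
#'   axioms.
#' @param ann Optional annotation data frame (see
#'   [read_annotations()]).
#' @param annotation_relation Label for entity-to-class edges.
#' @return A `RelGraph`: list with `nodes` (character) and `edges`
#'   (data frame `src`, `dst`, `label`, `directed`).
#' @export
build_graph <- function(o, ann = NULL,
                        annotation_relation = "hasAssociation") {
  ax <- o$axioms
  src <- dst <- lab <- character(0)
  dir <- logical(0)
  emit <- function(s, d, l, directed = TRUE) {
    src <<- c(src, s); dst <<- c(dst, d); lab <<- c(lab, l)
    dir <<- c(dir, directed)
  }
  for (i in seq_len(nrow(ax))) {
    s <- ax$subject[[i]]
    obj <- ax$object[[i]]
    kind <- ax$kind[[i]]
    if (kind == "SubClassOf") {
      if (obj$type == "class") emit(s, obj$id, "subClassOf")
      else if (obj$type == "some" && obj$filler$type == "class") {
        emit(s, obj$filler$id, obj$rel)
      }
    } else if (kind == "EquivalentTo") {
      if (obj$type == "class") {
        emit(s, obj$id, "equivalentTo"); emit(obj$id, s, "equivalentTo")
      } else if (obj$type == "some" && obj$filler$type == "class") {
        emit(s, obj$filler$id, obj$rel); emit(obj$filler$id, s, obj$rel)
      }
    } else if (kind == "DisjointWith") {
      emit(s, obj$id, "disjointWith")
    }
  }
  nodes <- unique(unlist(axiom_mentions(o), use.names = FALSE))
  if (!is.null(ann) && nrow(ann)) {
    pairs <- unique(ann[c("entity", "class")])
    for (i in seq_len(nrow(pairs))) {
      emit(pairs$entity[[i]], pairs$class[[i]], annotation_relation)
    }
    nodes <- c(nodes, pairs$entity, pairs$class)
  }
  edges <- unique(data.frame(src = src, dst = dst, label = lab,
                             directed = dir, stringsAsFactors = FALSE))
  edges <- edges[order(edges$src, edges$dst, edges$label, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(nodes)), edges = edges),
            class = "RelGraph")
}

#' @export
print.RelGraph <- function(x, ...) {
  cat("<RelGraph> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " labeled edges\n", sep = "")
  invisible(x)
}

#' Write a graph as an edge-list TSV
#'
#' Columns: `src`, `label`, `dst`, `directed`.
#'
#' @param g A `RelGraph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(g, path) {
  utils::write.table(g$edges[c("src", "label", "dst", "directed")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Biased random-walk parameters
#'
#' Second-order (Node2Vec) walk biases: from the previous node `t` at
#' current node `v`, the unnormalized weight of stepping to `x` is
#' `1/p` if `x == t` (return), `1` if `x` is a neighbor of `t`
#' (common neighborhood), and `1/q` otherwise (outward).
#'
#' @param p Return parameter (> 0).
#' @param q In-out parameter (> 0).
#' @param walk_length Nodes per walk (>= 1).
#' @param walks_per_node Walks started from each node (>= 1).
#' @param seed Integer seed; walks are bit-identical given the seed.
#' @return A `WalkParams` list.
#' @export
walk_params <- function(p = 1, q = 1, walk_length = 20L,
                        walks_per_node = 10L, seed = 1L) {
  stopifnot(p > 0, q > 0, walk_length >= 1L, walks_per_node >= 1L)
  structure(list(p = p, q = q, walk_length = as.integer(walk_length),
                 walks_per_node = as.integer(walks_per_node),
                 seed = as.integer(seed)),
            class = "WalkParams")
}

#' Generate biased random-walk sentences from a graph
#'
#' Emits `walks_per_node` walks of `walk_length` nodes from every node,
#' traversing edges without regard to direction (multi-edges collapse
#' to a single adjacency entry).  Isolated nodes yield single-node
#' sentences, so every graph node appears in the corpus vocabulary.
#'
#' @param g A `RelGraph`.
#' @param params A [walk_params()] object.
#' @return A `Corpus` of node-sequence sentences.
#' @export
generate_walks <- function(g, params = walk_params()) {
  nodes <- g$nodes
  if (!length(nodes)) return(corpus())
  n <- length(nodes)
  e_src <- match(g$edges$src, nodes)
  e_dst <- match(g$edges$dst, nodes)
  und <- unique(rbind(cbind(e_src, e_dst), cbind(e_dst, e_src)))
  und <- und[und[, 1L] != und[, 2L], , drop = FALSE]
  nbrs <- vector("list", n)
  if (nrow(und)) {
    ord <- order(und[, 1L], und[, 2L])
    und <- und[ord, , drop = FALSE]
    nbrs_split <- split(und[, 2L], und[, 1L])
    nbrs[as.integer(names(nbrs_split))] <- nbrs_split
  }
  inv_p <- 1 / params$p
  inv_q <- 1 / params$q
  L <- params$walk_length
  sent <- vector("list", n * params$walks_per_node)
  k <- 0L
  withr::with_seed(params$seed, {
    for (v0 in seq_len(n)) {
      for (w in seq_len(params$walks_per_node)) {
        k <- k + 1L
        nb <- nbrs[[v0]]
        if (is.null(nb) || L == 1L) {
          sent[[k]] <- nodes[[v0]]
          next
        }
        walk <- integer(L)
        walk[[1L]] <- v0
        walk[[2L]] <- nb[sample.int(length(nb), 1L)]
        i <- 2L
        while (i < L) {
          prev <- walk[[i - 1L]]
          cur <- walk[[i]]
          nb <- nbrs[[cur]]
          wt <- ifelse(nb == prev, inv_p,
                       ifelse(nb %in% nbrs[[prev]], 1, inv_q))
          walk[[i + 1L]] <- nb[sample.int(length(nb), 1L, prob = wt)]
          i <- i + 1L
        }
        sent[[k]] <- nodes[walk]
      }
    }
  })
  corpus(sent)
}
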