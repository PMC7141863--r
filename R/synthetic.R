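# Synthetic studies with the causal structure of inter-ontology
# axioms: functional modules whose member classes sit far apart in the
# primary hierarchy but point, via existential bridge axioms, at a
# common class of a small external ontology.  The interaction signal
# between annotated entities flows exclusively through those bridges,
# so withholding the bridge file from the pipeline ablates exactly the
# quantity of interest while the biological data (annotations and
# positive pairs) stay fixed.

#' Configuration of a synthetic ablation study
#'
#' @param n_entities Number of annotated entities.
#' @param n_primary_classes Classes in the primary ontology (a random
#'   rooted tree).
#' @param n_external_classes Classes in the external ontology.
#' @param n_modules Number of functional modules; each module's member
#'   leaves share one external bridge target.
#' @param module_size Leaves per module; module members are scattered
#'   round-robin across different root branches so that they are
#'   mutually distant in the primary hierarchy.
#' @param annotations_per_entity Annotated classes per entity: one leaf
#'   of the entity's home module plus noise leaves drawn from the
#'   module-free leaf pool.
#' @param link_probability Probability that a module member receives
#'   its bridge axiom (rho).
#' @param pi1,pi0 Interaction probability for pairs connected through a
#'   shared external class (pi1) and for background pairs (pi0);
#'   `pi0 > 0` keeps the task non-separable.
#' @param metadata_signal `"none"` or `"labels-share-module-words"`.
#' @param prefix_primary,prefix_external CURIE prefixes of the two
#'   ontologies.
#' @param seed Integer seed; generation is fully deterministic.
#' @return A `SynthConfig` list.
#' @export
synth_config <- function(n_entities = 300L, n_primary_classes = 120L,
                         n_external_classes = 8L, n_modules = 8L,
                         module_size = 6L, annotations_per_entity = 3L,
                         link_probability = 0.9, pi1 = 0.35, pi0 = 0.03,
                         metadata_signal = c("none",
                                             "labels-share-module-words"),
                         prefix_primary = "PRI", prefix_external = "EXT",
                         seed = 1L) {
  metadata_signal <- match.arg(metadata_signal)
  stopifnot(pi0 >= 0, pi1 >= pi0, pi1 <= 1,
            link_probability >= 0, link_probability <= 1,
            n_modules <= n_external_classes,
            annotations_per_entity >= 1L, module_size >= 1L)
  structure(list(n_entities = as.integer(n_entities),
                 n_primary_classes = as.integer(n_primary_classes),
                 n_external_classes = as.integer(n_external_classes),
                 n_modules = as.integer(n_modules),
                 module_size = as.integer(module_size),
                 annotations_per_entity = as.integer(annotations_per_entity),
                 link_probability = link_probability,
                 pi1 = pi1, pi0 = pi0, metadata_signal = metadata_signal,
                 prefix_primary = prefix_primary,
                 prefix_external = prefix_external,
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

synth_curie <- function(prefix, i) sprintf("%s:%07d", prefix, i)

# Random rooted tree as a parent vector; the first few non-root nodes
# attach to the root so that several major branches always exist.
random_tree_parents <- function(n) {
  if (n < 2L) return(integer(0))
  parents <- integer(n)
  for (i in 2:n) {
    parents[i] <- if (i <= 6L) 1L else sample.int(i - 1L, 1L)
  }
  parents[-1L]
}

#' Generate a synthetic ablation study
#'
#' Writes, under `dir`: `primary.obo` (the primary hierarchy, with
#' labels per the metadata-signal setting), `external.obo` (the small
#' external hierarchy), `bridge.axioms` (inter-ontology existential
#' axioms, axiom-lines format), `annotations.tsv` (entity-class TSV),
#' `positives.tsv` (positive entity pairs) and `truth.json` (generator
#' bookkeeping: module membership, per-entity bridge targets, linked
#' pair counts).  Unordered entity pairs interact with probability
#' `pi1` when their annotation sets reach a common external class
#' through bridge axioms and `pi0` otherwise.  The positive-pair file
#' depends only on the configuration, never on which ontology files a
#' downstream pipeline chooses to read.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file `paths` and the `truth`
#'   record.
#' @export
generate_study <- function(cfg, dir = tempfile("synthstudy")) {
  stopifnot(inherits(cfg, "SynthConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- withr::with_seed(cfg$seed, generate_study_impl(cfg, dir))
  invisible(res)
}

generate_study_impl <- function(cfg, dir) {
  np <- cfg$n_primary_classes
  pri <- synth_curie(cfg$prefix_primary, seq_len(np))
  parents <- random_tree_parents(np)
  pri_axioms <- lapply(2:np, function(i) {
    axiom("SubClassOf", pri[i], pri[parents[i - 1L]], source = "primary")
  })
  is_leaf <- !(seq_len(np) %in% parents)
  leaves <- which(is_leaf)

  # branch (child-of-root subtree) of every node
  branch <- integer(np)
  for (i in 2:np) {
    j <- i
    while (parents[j - 1L] != 1L) j <- parents[j - 1L]
    branch[i] <- j
  }

  n_slots <- cfg$n_modules * cfg$module_size
  if (length(leaves) < n_slots) {
    stop("infeasible sizes: ", length(leaves), " leaves cannot fill ",
         cfg$n_modules, " modules of ", cfg$module_size)
  }
  # scatter module members: fill module slots (module-major, so
  # consecutive slots belong to the same module) by cycling round-robin
  # over branches, popping one unused leaf from each branch in turn --
  # a module's members therefore land on distinct root branches
  shuf <- sample(leaves)
  by_branch <- split(shuf, branch[shuf])
  order_br <- names(by_branch)
  picked <- integer(0)
  bi <- 0L
  while (length(picked) < n_slots) {
    bi <- bi + 1L
    br <- order_br[((bi - 1L) %% length(order_br)) + 1L]
    if (length(by_branch[[br]]) == 0L) {
      if (all(vapply(by_branch, length, integer(1)) == 0L)) break
      next
    }
    picked <- c(picked, by_branch[[br]][1L])
    by_branch[[br]] <- by_branch[[br]][-1L]
  }
  if (length(picked) < n_slots) stop("infeasible module assignment")
  module_of <- rep(seq_len(cfg$n_modules), each = cfg$module_size)
  names(module_of) <- pri[picked]
  free_leaves <- pri[setdiff(leaves, picked)]
  if (length(free_leaves) < cfg$annotations_per_entity - 1L) {
    stop("infeasible sizes: not enough module-free leaves for noise ",
         "annotations")
  }

  ne <- cfg$n_external_classes
  ext <- synth_curie(cfg$prefix_external, seq_len(ne))
  ext_parents <- random_tree_parents(ne)
  ext_axioms <- if (ne >= 2L) {
    lapply(2:ne, function(i) {
      axiom("SubClassOf", ext[i], ext[ext_parents[i - 1L]],
            source = "external")
    })
  } else list()
  # bridge targets: prefer non-root external classes
  targets <- ext[rev(seq_len(ne))[seq_len(cfg$n_modules)]]

  bridged <- stats::runif(n_slots) < cfg$link_probability
  bridge_axioms <- lapply(which(bridged), function(k) {
    axiom("SubClassOf", names(module_of)[k],
          ce_some("related_to", targets[module_of[k]]), source = "bridge")
  })

  # entities: one home-module leaf + noise leaves from the free pool
  entities <- sprintf("P%03d", seq_len(cfg$n_entities))
  home <- sample.int(cfg$n_modules, cfg$n_entities, replace = TRUE)
  ann_entity <- character(0)
  ann_class <- character(0)
  entity_leaf <- character(cfg$n_entities)
  for (i in seq_len(cfg$n_entities)) {
    members <- names(module_of)[module_of == home[i]]
    lf <- members[sample.int(length(members), 1L)]
    entity_leaf[i] <- lf
    noise <- free_leaves[sample.int(length(free_leaves),
                                    cfg$annotations_per_entity - 1L)]
    ann_entity <- c(ann_entity, rep(entities[i], cfg$annotations_per_entity))
    ann_class <- c(ann_class, lf, noise)
  }

  # an entity reaches an external class iff its module leaf is bridged
  leaf_target <- rep(NA_character_, n_slots)
  leaf_target[bridged] <- targets[module_of[bridged]]
  names(leaf_target) <- names(module_of)
  entity_target <- unname(leaf_target[entity_leaf])

  # pairwise linked status and interaction draws
  idx <- utils::combn(cfg$n_entities, 2L)
  linked <- !is.na(entity_target[idx[1L, ]]) &
    !is.na(entity_target[idx[2L, ]]) &
    entity_target[idx[1L, ]] == entity_target[idx[2L, ]]
  p <- ifelse(linked, cfg$pi1, cfg$pi0)
  positive <- stats::runif(length(p)) < p
  pos_pairs <- data.frame(entity_a = entities[idx[1L, positive]],
                          entity_b = entities[idx[2L, positive]],
                          stringsAsFactors = FALSE)

  primary <- plant_labels(ontology_set(pri_axioms), cfg, module_of)
  external <- ontology_set(ext_axioms)
  bridge <- ontology_set(bridge_axioms)

  paths <- list(primary = file.path(dir, "primary.obo"),
                external = file.path(dir, "external.obo"),
                bridge = file.path(dir, "bridge.axioms"),
                annotations = file.path(dir, "annotations.tsv"),
                positives = file.path(dir, "positives.tsv"),
                truth = file.path(dir, "truth.json"))
  write_ontology(primary, paths$primary, format = "obo")
  write_ontology(external, paths$external, format = "obo")
  write_ontology(bridge, paths$bridge, format = "axiom-lines")
  utils::write.table(data.frame(ann_entity, ann_class),
                     paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(pos_pairs, paths$positives, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  truth <- list(
    config = unclass(cfg),
    module_of = as.list(module_of),
    module_targets = stats::setNames(as.list(targets),
                                     paste0("module", seq_len(cfg$n_modules))),
    entity_home_module = stats::setNames(as.list(home), entities),
    entity_module_leaf = stats::setNames(as.list(entity_leaf), entities),
    entity_target = stats::setNames(as.list(entity_target), entities),
    n_pairs_total = ncol(idx),
    n_pairs_linked = sum(linked),
    n_positive = sum(positive),
    n_positive_linked = sum(positive & linked),
    n_positive_unlinked = sum(positive & !linked))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  list(paths = paths, truth = truth, dir = dir)
}

# Label planting: module members share a module-specific marker word;
# all other label words come from a common noise vocabulary.  With the
# signal off, every word is noise and no word is module-predictive.
plant_labels <- function(primary, cfg, module_of) {
  classes <- sort(unique(c(primary$axioms$subject,
                           unlist(lapply(primary$axioms$object, expr_classes),
                                  use.names = FALSE))))
  noise_vocab <- sprintf("nsw%03d", 1:60)
  labels <- vapply(classes, function(cl) {
    words <- noise_vocab[sample.int(length(noise_vocab), 3L)]
    if (cfg$metadata_signal == "labels-share-module-words" &&
        cl %in% names(module_of)) {
      words <- c(sprintf("mkw%02d", module_of[[cl]]), words[1:2])
    }
    paste(words, collapse = " ")
  }, character(1))
  md <- data.frame(subject = classes, property = "label",
                   text = unname(labels), stringsAsFactors = FALSE)
  ontology_set(primary$axioms, metadata = md)
}

#' Re-plant class labels for a generated study
#'
#' Rewrites `primary.obo` with fresh labels under the given
#' metadata-signal setting, leaving axioms, annotations and positive
#' pairs untouched.  Useful for contrasting informative labels
#' (module members share a marker word) with pure-noise labels on an
#' otherwise identical study.
#'
#' @param cfg A [synth_config()] (its `metadata_signal` and `seed` are
#'   used).
#' @param study The list returned by [generate_study()].
#' @return Invisibly, the path of the rewritten `primary.obo`.
#' @export
plant_metadata <- function(cfg, study) {
  primary <- parse_ontology(study$paths$primary, format = "obo")
  module_of <- unlist(study$truth$module_of)
  bare <- ontology_set(primary$axioms)  # drop existing labels
  relabeled <- withr::with_seed(cfg$seed + 7L,
                                plant_labels(bare, cfg, module_of))
  write_ontology(relabeled, study$paths$primary, format = "obo")
  invisible(study$paths$primary)
}
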