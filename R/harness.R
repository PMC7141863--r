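# Ablation harness: one shared annotation/pair dataset, a list of
# ontology variants, and a comparative report.  Training and testing
# data stay fixed across variants (the dataset is built once and its
# fingerprint asserted); only the background ontology changes, and
# embeddings are retrained from scratch per variant because the corpus
# changes with the ontology.

`%||%` <- function(a, b) if (is.null(a)) b else a

derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 7919 + salt) %% 2147483647)
}

#' Assemble, encode, embed, score and evaluate one ontology variant
#'
#' The shared single-variant pipeline: saturate the ontology (unless
#' disabled), encode it as a corpus (logical axioms + annotations;
#' optionally metadata sentences; or biased graph walks), train
#' skip-gram embeddings, score the dataset's test pairs and compute
#' the ROC/AUC.
#'
#' @param o An `OntologySet`.
#' @param ann Annotation data frame.
#' @param dataset A `PairDataset`.
#' @param encoder `"axiom-corpus"`, `"axiom+metadata-corpus"` or
#'   `"graph-walks"`.
#' @param scorer `"cosine"` or `"nn"`.
#' @param embedding A [skipgram_params()] object.
#' @param nn An [nn_config()] object (used when `scorer = "nn"`).
#' @param walks A [walk_params()] object (used by the graph encoder).
#' @param inference Apply [saturate()] first (default `TRUE`).
#' @param metadata_properties Properties for the metadata encoder.
#' @return List with `auc`, `eval` (an `EvalResult`), `scores` (a
#'   `ScoreSet` on the test split) and `n_axioms`.
#' @export
evaluate_variant <- function(o, ann, dataset,
                             encoder = c("axiom-corpus",
                                         "axiom+metadata-corpus",
                                         "graph-walks"),
                             scorer = c("cosine", "nn"),
                             embedding = skipgram_params(),
                             nn = nn_config(),
                             walks = walk_params(),
                             inference = TRUE,
                             metadata_properties = c("label", "synonym",
                                                     "definition")) {
  encoder <- match.arg(encoder)
  scorer <- match.arg(scorer)
  if (inference) o <- saturate(o)
  corp <- switch(encoder,
    "axiom-corpus" = build_logical_corpus(o, ann),
    "axiom+metadata-corpus" = corpus_append(
      build_logical_corpus(o, ann),
      build_metadata_corpus(o, properties = metadata_properties)),
    "graph-walks" = generate_walks(build_graph(o, ann), walks))
  emb <- train_embeddings(corp, embedding)
  test <- dataset[dataset$split == "test", , drop = FALSE]
  scores <- if (scorer == "cosine") {
    cosine_scores(emb, test)
  } else {
    nn_fit_and_score(emb, dataset, nn)
  }
  ev <- roc_auc(scores, test)
  list(auc = ev$auc, eval = ev, scores = scores, n_axioms = n_axioms(o))
}

parse_variant <- function(v) {
  if (grepl("^plus-ns:", v)) {
    list(type = "plus-ns", prefix = sub("^plus-ns:", "", v))
  } else if (grepl("^substitute:", v)) {
    list(type = "substitute", prefix = sub("^substitute:", "", v))
  } else if (v %in% c("base", "plus", "plus-external", "plus-metadata")) {
    list(type = v, prefix = NULL)
  } else {
    stop("unknown variant: ", v)
  }
}

#' Run an ablation experiment over ontology variants
#'
#' Reads the base ontology (and optionally an enriched "plus" axiom
#' set and full external ontologies), builds one labeled pair dataset,
#' and for every requested variant assembles the ontology, runs
#' [evaluate_variant()] and compares the result against the `base`
#' variant.  Variants:
#' \describe{
#'   \item{`base`}{the base ontology alone}
#'   \item{`plus`}{base merged with the enriched axiom set(s)}
#'   \item{`plus-ns:<PREFIX>`}{the plus set restricted to base-internal
#'     axioms plus links into `<PREFIX>`}
#'   \item{`plus-external`}{the plus set merged with every supplied
#'     external ontology's full axiom set}
#'   \item{`plus-metadata`}{the plus set encoded with metadata
#'     sentences included}
#'   \item{`substitute:<PREFIX>`}{the base set with its `<PREFIX>`
#'     sub-ontology replaced by the plus set}
#' }
#'
#' @param config Named list (or YAML path via
#'   [read_experiment_config()]) with keys: `base_ontology`,
#'   `base_format`, `plus_ontology` (path or vector of paths),
#'   `plus_format`, `external_ontologies` (named list prefix -> path),
#'   `annotations`, `annotation_dialect`, `excluded_evidence`,
#'   `positive_pairs`, `variants`, `encoder`, `scorer`,
#'   `negative_ratio`, `split_fraction`, `seed`, `embedding` (list of
#'   [skipgram_params()] arguments), `nn`, `walks`, `inference`,
#'   `comparison` (method for [compare_models()]), `p_adjust`
#'   (`"none"` or `"BH"`).
#' @return An `AblationReport`: data frame with one row per variant
#'   (`variant`, `auc`, `n_axioms`, `n_pos`, `n_neg`, `delta_vs_base`,
#'   `p_vs_base`), with the per-variant evaluations in attribute
#'   `evals` and the dataset fingerprint in attribute `fingerprint`.
#' @export
run_experiment <- function(config) {
  cfg <- config
  base <- parse_ontology(cfg$base_ontology,
                         format = cfg$base_format %||% "obo")
  plus_paths <- cfg$plus_ontology
  plus <- base
  for (p in plus_paths) {
    fmt <- cfg$plus_format %||%
      (if (grepl("\\.obo$", p)) "obo" else "axiom-lines")
    plus <- merge_or_substitute(plus, parse_ontology(p, format = fmt))
  }
  externals <- lapply(cfg$external_ontologies, function(p) {
    fmt <- if (grepl("\\.obo$", p)) "obo" else "axiom-lines"
    parse_ontology(p, format = fmt)
  })

  ann <- read_annotations(cfg$annotations,
                          dialect = cfg$annotation_dialect %||% "tsv",
                          excluded_evidence = cfg$excluded_evidence %||%
                            character())
  positives <- read_positive_pairs(cfg$positive_pairs)
  universe <- sort(unique(ann$entity))
  known <- positives$entity_a %in% universe & positives$entity_b %in% universe
  n_dropped <- sum(!known)
  positives <- positives[known, , drop = FALSE]

  seed <- cfg$seed %||% 1L
  dataset <- build_pair_dataset(positives, universe,
                                negative_ratio = cfg$negative_ratio %||% 1,
                                split_fraction = cfg$split_fraction %||% 0.7,
                                seed = derive_seed(seed, 1L))
  fingerprint <- pair_dataset_fingerprint(dataset)

  emb_args <- cfg$embedding; emb_args$seed <- NULL
  nn_args <- cfg$nn; nn_args$seed <- NULL
  walk_args <- cfg$walks; walk_args$seed <- NULL
  embedding <- do.call(skipgram_params,
                       c(emb_args, list(seed = derive_seed(seed, 2L))))
  nn <- do.call(nn_config, c(nn_args, list(seed = derive_seed(seed, 3L))))
  walks <- do.call(walk_params, c(walk_args, list(seed = derive_seed(seed, 4L))))
  encoder <- cfg$encoder %||% "axiom-corpus"
  scorer <- cfg$scorer %||% "cosine"
  base_prefix <- cfg$base_prefix %||% base$prefixes[[1L]]

  variants <- cfg$variants %||% c("base", "plus")
  evals <- vector("list", length(variants))
  rows <- vector("list", length(variants))
  for (k in seq_along(variants)) {
    v <- parse_variant(variants[[k]])
    o <- switch(v$type,
      base = base,
      plus = plus,
      "plus-ns" = restrict_to_namespace_links(plus, v$prefix, base_prefix),
      "plus-external" = Reduce(merge_or_substitute, externals, plus),
      "plus-metadata" = plus,
      substitute = merge_or_substitute(base, plus, v$prefix))
    enc <- if (v$type == "plus-metadata") "axiom+metadata-corpus" else encoder
    stopifnot(identical(pair_dataset_fingerprint(dataset), fingerprint))
    evals[[k]] <- evaluate_variant(o, ann, dataset, encoder = enc,
                                   scorer = scorer, embedding = embedding,
                                   nn = nn, walks = walks,
                                   inference = cfg$inference %||% TRUE)
    rows[[k]] <- data.frame(variant = variants[[k]], auc = evals[[k]]$auc,
                            n_axioms = evals[[k]]$n_axioms,
                            n_pos = evals[[k]]$eval$n_pos,
                            n_neg = evals[[k]]$eval$n_neg,
                            stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)

  ref <- match("base", report$variant)
  if (is.na(ref)) ref <- 1L
  test <- dataset[dataset$split == "test", , drop = FALSE]
  delta <- p <- rep(NA_real_, nrow(report))
  for (k in seq_len(nrow(report))) {
    if (k == ref) next
    cmpm <- compare_models(evals[[k]]$scores, evals[[ref]]$scores, test,
                           method = cfg$comparison %||% "paired-bootstrap",
                           seed = derive_seed(seed, 100L + k))
    delta[k] <- cmpm$delta
    p[k] <- cmpm$p_value
  }
  if (identical(cfg$p_adjust %||% "none", "BH")) {
    p[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  }
  report$delta_vs_base <- delta
  report$p_vs_base <- p
  structure(report, class = c("AblationReport", "data.frame"),
            evals = evals, fingerprint = fingerprint,
            n_dropped_positives = n_dropped)
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file path.
#' @return A named list suitable for [run_experiment()].
#' @export
read_experiment_config <- function(path) yaml::read_yaml(path)

#' Write an ablation report as TSV
#'
#' One row per variant with AUC, axiom count, pair counts and the
#' delta/p-value against the base variant.
#'
#' @param report An `AblationReport`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Translate pair endpoints through a many-to-many identifier map
#'
#' Each endpoint is replaced by all of its mapped identifiers
#' (cartesian expansion); pairs with an unmapped endpoint are dropped
#' and counted in the `dropped` attribute.  Used, for example, to carry
#' gene pairs across species through an orthology table.
#'
#' @param pairs Two-column data frame (`entity_a`, `entity_b`).
#' @param map A two-column data frame `(from, to)` or the path of a
#'   headerless two-column TSV.
#' @return Data frame of translated pairs (deduplicated), with
#'   attribute `dropped` = number of input pairs lost to unmapped
#'   endpoints.
#' @export
apply_id_map <- function(pairs, map) {
  if (is.character(map) && length(map) == 1L) {
    map <- utils::read.delim(map, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
  }
  map <- stats::setNames(as.data.frame(map, stringsAsFactors = FALSE)[1:2],
                         c("from", "to"))
  to_of <- split(map$to, map$from)
  a <- as.character(pairs[[1L]])
  b <- as.character(pairs[[2L]])
  out_a <- character(0)
  out_b <- character(0)
  dropped <- 0L
  for (i in seq_along(a)) {
    ta <- to_of[[a[i]]]
    tb <- to_of[[b[i]]]
    if (is.null(ta) || is.null(tb)) {
      dropped <- dropped + 1L
      next
    }
    grid <- expand.grid(ta, tb, stringsAsFactors = FALSE)
    out_a <- c(out_a, grid[[1L]])
    out_b <- c(out_b, grid[[2L]])
  }
  out <- unique(data.frame(entity_a = out_a, entity_b = out_b,
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  structure(out, dropped = dropped)
}
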