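# Labeled entity-pair datasets: positives from an interaction list,
# negatives sampled uniformly from non-edges, and a label-stratified
# train/test split at a fixed fraction (70/30 by default, no
# cross-validation).  Pairs are unordered throughout.

canonical_pairs <- function(a, b) {
  data.frame(entity_a = pmin(a, b), entity_b = pmax(a, b),
             stringsAsFactors = FALSE)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# bijection between unordered pairs over 1..n (i < j) and 1..n(n-1)/2,
# enumerated in row-major order
decode_pair_index <- function(k, n) {
  cum <- c(0, cumsum((n - 1):1))
  i <- findInterval(k - 0.5, cum)
  j <- i + (k - cum[i])
  cbind(i, j)
}

#' Build a labeled pair dataset with sampled negatives and a split
#'
#' Negatives are drawn uniformly without replacement from the non-self,
#' non-positive unordered pairs of the universe, `round(negative_ratio
#' * n_positives)` of them (capped, with a warning, at the number of
#' available pairs).  The train/test split is random, stratified by
#' label, at `split_fraction` (pair-level: an entity may appear in both
#' splits, which mirrors the evaluation procedure this package
#' implements; pass `entity_disjoint = TRUE` for the stricter variant
#' in which test entities are held out entirely).  Deterministic given
#' `seed`.
#'
#' @param positives Two-column data frame/matrix of positive pairs.
#' @param universe Character vector of all entities.
#' @param negative_ratio Negatives per positive.
#' @param split_fraction Fraction of records assigned to `train`.
#' @param seed Integer seed.
#' @param entity_disjoint If `TRUE`, split entities (not pairs) and
#'   keep only pairs internal to one side.
#' @return A `PairDataset`: data frame with columns `entity_a`,
#'   `entity_b`, `label` (0/1) and `split` (`train`/`test`).
#' @export
build_pair_dataset <- function(positives, universe, negative_ratio = 1,
                               split_fraction = 0.7, seed = 1L,
                               entity_disjoint = FALSE) {
  stopifnot(split_fraction > 0, split_fraction < 1, negative_ratio >= 0)
  universe <- sort(unique(as.character(universe)))
  n <- length(universe)
  positives <- as.data.frame(positives, stringsAsFactors = FALSE)
  pos <- canonical_pairs(as.character(positives[[1L]]),
                         as.character(positives[[2L]]))
  pos <- unique(pos)
  if (any(pos$entity_a == pos$entity_b)) stop("self-pairs are not allowed")
  if (!all(c(pos$entity_a, pos$entity_b) %in% universe)) {
    stop("positive pairs mention entities outside the universe")
  }
  ia <- match(pos$entity_a, universe)
  ib <- match(pos$entity_b, universe)
  # index of unordered pair (i < j): pairs before row i, plus offset
  pos_idx <- c(0, cumsum((n - 1):1))[ia] + (ib - ia)
  total <- n * (n - 1) / 2
  n_neg <- round(negative_ratio * nrow(pos))
  avail <- total - nrow(pos)
  if (n_neg > avail) {
    warning("universe supplies only ", avail, " negative pairs; capping")
    n_neg <- avail
  }
  withr::with_seed(seed, {
    neg_idx <- if (n_neg == 0) integer(0) else if (total <= 2e6) {
      pool <- seq_len(total)[-pos_idx]
      pool[sample.int(length(pool), n_neg)]
    } else {
      found <- integer(0)
      while (length(found) < n_neg) {
        cand <- sample.int(total, n_neg)
        cand <- setdiff(cand, c(pos_idx, found))
        found <- c(found, cand)
      }
      found[seq_len(n_neg)]
    }
    neg_ij <- decode_pair_index(neg_idx, n)
    neg_df <- if (length(neg_idx)) {
      data.frame(entity_a = universe[neg_ij[, 1L]],
                 entity_b = universe[neg_ij[, 2L]],
                 label = 0L, stringsAsFactors = FALSE)
    } else {
      data.frame(entity_a = character(), entity_b = character(),
                 label = integer(), stringsAsFactors = FALSE)
    }
    df <- rbind(
      data.frame(entity_a = pos$entity_a, entity_b = pos$entity_b,
                 label = 1L, stringsAsFactors = FALSE),
      neg_df)
    df <- df[order(-df$label, df$entity_a, df$entity_b, method = "radix"), ,
             drop = FALSE]
    rownames(df) <- NULL
    df$split <- "test"
    if (entity_disjoint) {
      tr_ent <- sample(universe, round(split_fraction * n))
      in_tr <- df$entity_a %in% tr_ent & df$entity_b %in% tr_ent
      in_te <- !(df$entity_a %in% tr_ent) & !(df$entity_b %in% tr_ent)
      df <- df[in_tr | in_te, , drop = FALSE]
      df$split <- ifelse(in_tr[in_tr | in_te], "train", "test")
      rownames(df) <- NULL
    } else {
      for (l in c(1L, 0L)) {
        rows <- which(df$label == l)
        tr <- sample(rows, round(split_fraction * length(rows)))
        df$split[tr] <- "train"
      }
    }
  })
  structure(df, class = c("PairDataset", "data.frame"), seed = seed,
            split_fraction = split_fraction, negative_ratio = negative_ratio)
}

#' Read and write pair datasets as TSV
#'
#' `write_pair_dataset` emits a header and the four columns
#' `entity_a`, `entity_b`, `label`, `split`.  `read_positive_pairs`
#' reads a headerless two-column TSV of interacting pairs (the usual
#' interaction-database export shape).
#'
#' @param d A `PairDataset`.
#' @param path File path.
#' @return The dataset (readers) or `path` invisibly (writer).
#' @export
write_pair_dataset <- function(d, path) {
  utils::write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_dataset
#' @export
read_pair_dataset <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(entity_a = "character",
                                         entity_b = "character"))
  stopifnot(all(c("entity_a", "entity_b", "label", "split") %in% names(df)))
  structure(df, class = c("PairDataset", "data.frame"))
}

#' @rdname write_pair_dataset
#' @export
read_positive_pairs <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("expected two tab-separated columns in ", path)
  stats::setNames(df[1:2], c("entity_a", "entity_b"))
}

#' One-line fingerprint of a pair dataset
#'
#' Used to assert that the dataset (records, labels and split) is
#' byte-identical across ablation variants.
#'
#' @param d A `PairDataset`.
#' @return A single string.
#' @export
pair_dataset_fingerprint <- function(d) {
  paste(d$entity_a, d$entity_b, d$label, d$split, sep = ",", collapse = ";")
}

#' Score entity pairs by cosine similarity of their embeddings
#'
#' Standard cosine similarity, symmetric in pair order.  Missing
#' embeddings and zero vectors raise errors naming the offending
#' token.
#'
#' @param t An `EmbeddingTable`.
#' @param pairs Data frame with columns `entity_a`, `entity_b` (a
#'   `PairDataset` works).
#' @return A `ScoreSet`: data frame `entity_a`, `entity_b`, `score`
#'   with attribute `scorer = "cosine"`.
#' @export
cosine_scores <- function(t, pairs) {
  a <- as.character(pairs$entity_a)
  b <- as.character(pairs$entity_b)
  va <- get_vectors(t, a)
  vb <- get_vectors(t, b)
  na_ <- sqrt(rowSums(va^2))
  nb_ <- sqrt(rowSums(vb^2))
  zero <- c(a[na_ == 0], b[nb_ == 0])
  if (length(zero)) {
    stop("zero embedding vector for token(s): ",
         paste(unique(zero), collapse = ", "))
  }
  s <- rowSums(va * vb) / (na_ * nb_)
  structure(data.frame(entity_a = a, entity_b = b, score = s,
                       stringsAsFactors = FALSE),
            class = c("ScoreSet", "data.frame"), scorer = "cosine")
}
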