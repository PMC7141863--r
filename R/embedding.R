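# Skip-gram embedding training on sentence corpora, plus persistence in
# the word2vec text format.

#' Skip-gram training parameters
#'
#' Skip-gram with negative sampling is used (rather than CBOW): corpus
#' sentences are short and entity tokens rare, the regime skip-gram
#' handles best.  `min_count = 1` by default so that every annotated
#' entity and every mentioned class receives a vector — pair scoring
#' fails loudly on missing tokens.  Training is single-threaded and
#' bit-identical across runs for a fixed seed.
#'
#' @param dimension Embedding dimension (>= 1).
#' @param window Maximum context window (the effective window is shrunk
#'   uniformly per position, as in standard word2vec).
#' @param min_count Minimum corpus frequency for a token to be
#'   embedded.
#' @param negative_samples Negative samples per positive pair.
#' @param epochs Passes over the corpus.
#' @param seed Integer seed.
#' @param threads Kept for interface compatibility; execution is always
#'   single-threaded (the deterministic mode).
#' @param alpha,min_alpha Initial and floor learning rate (linear
#'   decay).
#' @param sample Frequent-word subsampling threshold (0 disables): an
#'   occurrence of a token with corpus frequency share `f` is kept with
#'   probability `(sqrt(f/sample) + 1) * sample / f`.  Keeps ubiquitous
#'   keyword tokens (`SubClassOf`, `some`, ...) from dominating the
#'   co-occurrence statistics.
#' @return A `SkipgramParams` list.
#' @export
skipgram_params <- function(dimension = 200L, window = 5L, min_count = 1L,
                            negative_samples = 5L, epochs = 10L, seed = 1L,
                            threads = 1L, alpha = 0.025, min_alpha = 1e-4,
                            sample = 1e-3) {
  stopifnot(dimension >= 1L, min_count >= 1L, window >= 1L,
            negative_samples >= 0L, epochs >= 1L, sample >= 0)
  structure(list(dimension = as.integer(dimension),
                 window = as.integer(window),
                 min_count = as.integer(min_count),
                 negative_samples = as.integer(negative_samples),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 threads = as.integer(threads),
                 alpha = alpha, min_alpha = min_alpha, sample = sample),
            class = "SkipgramParams")
}

#' Skip-gram settings for study-scale corpora
#'
#' The [skipgram_params()] defaults target real ontology corpora
#' (millions of tokens).  Synthetic studies produce corpora around
#' 10^4 tokens, where a smaller dimension and many more passes are
#' appropriate; these settings (dimension 50, 150 epochs, 10 negative
#' samples) are used throughout the package's own synthetic
#' experiments.
#'
#' @param seed Integer seed.
#' @return A `SkipgramParams` list.
#' @export
study_embedding_params <- function(seed = 1L) {
  skipgram_params(dimension = 50L, epochs = 150L, negative_samples = 10L,
                  seed = seed)
}

#' Train skip-gram embeddings on a corpus
#'
#' Builds the vocabulary (tokens with frequency >= `min_count`, ordered
#' by decreasing frequency then token), then trains skip-gram with
#' negative sampling in compiled code.  With a fixed seed the returned
#' table is bit-identical across runs.
#'
#' @param x A `Corpus`.
#' @param params A [skipgram_params()] object.
#' @param init Optional `EmbeddingTable` of the same dimension used to
#'   warm-start vectors of shared tokens (two-phase background
#'   pre-training).
#' @return An `EmbeddingTable`: list with `dimension` and `vectors`
#'   (numeric matrix, one named row per token).
#' @export
train_embeddings <- function(x, params = skipgram_params(), init = NULL) {
  stopifnot(inherits(x, "Corpus"))
  if (!length(x)) stop("cannot train embeddings on an empty corpus")
  toks <- unlist(x, use.names = FALSE)
  freq <- table(toks)
  freq <- freq[freq >= params$min_count]
  if (!length(freq)) stop("no token reaches min_count = ", params$min_count)
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  vocab <- names(freq)[ord]
  counts <- as.numeric(freq)[ord]

  sent_idx <- lapply(x, function(s) {
    i <- match(s, vocab)
    as.integer(i[!is.na(i)] - 1L)
  })
  sent_idx <- sent_idx[vapply(sent_idx, length, integer(1)) > 0L]

  init_idx <- integer(0)
  init_vec <- matrix(numeric(0), nrow = 0L, ncol = params$dimension)
  if (!is.null(init)) {
    stopifnot(inherits(init, "EmbeddingTable"))
    if (init$dimension != params$dimension) {
      stop("init table dimension (", init$dimension,
           ") does not match params dimension (", params$dimension, ")")
    }
    shared <- intersect(vocab, rownames(init$vectors))
    if (length(shared)) {
      init_idx <- match(shared, vocab) - 1L
      init_vec <- init$vectors[shared, , drop = FALSE]
    }
  }

  m <- sgns_train_cpp(sent_idx, length(vocab), params$dimension,
                      params$window, params$negative_samples,
                      params$epochs, params$alpha, params$min_alpha,
                      params$sample, counts, as.double(params$seed),
                      as.integer(init_idx), init_vec)
  rownames(m) <- vocab
  structure(list(dimension = params$dimension, vectors = m),
            class = "EmbeddingTable")
}

#' @export
print.EmbeddingTable <- function(x, ...) {
  cat("<EmbeddingTable> ", nrow(x$vectors), " tokens x ", x$dimension,
      " dimensions\n", sep = "")
  invisible(x)
}

#' Look up embedding vectors, failing loudly on missing tokens
#'
#' @param t An `EmbeddingTable`.
#' @param tokens Character vector of tokens.
#' @return Numeric matrix with one row per requested token.
#' @export
get_vectors <- function(t, tokens) {
  miss <- setdiff(unique(tokens), rownames(t$vectors))
  if (length(miss)) {
    stop("no embedding for token(s): ",
         paste(utils::head(miss, 10L), collapse = ", "))
  }
  t$vectors[tokens, , drop = FALSE]
}

#' Save and load embeddings in the word2vec text format
#'
#' Header line `<vocab_size> <dimension>`, then one line per token:
#' the token followed by its coordinates, written with 17 significant
#' digits so that `load_vectors(save_vectors(t))` reproduces the table
#' to within 1e-12.
#'
#' @param t An `EmbeddingTable`.
#' @param path File path.
#' @return `save_vectors` returns `path` invisibly; `load_vectors`
#'   returns an `EmbeddingTable`.
#' @export
save_vectors <- function(t, path) {
  m <- t$vectors
  header <- paste(nrow(m), t$dimension)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(rownames(m)[i], paste(sprintf("%.17g", m[i, ]), collapse = " "))
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname save_vectors
#' @export
load_vectors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty vector file: ", path)
  hdr <- strsplit(trimws(lines[[1L]]), "[[:space:]]+")[[1L]]
  if (length(hdr) != 2L) stop("malformed header in ", path)
  n <- as.integer(hdr[[1L]])
  dim <- as.integer(hdr[[2L]])
  if (length(lines) - 1L != n) {
    stop("header announces ", n, " rows but file has ", length(lines) - 1L)
  }
  m <- matrix(0, nrow = n, ncol = dim)
  toks <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[[i + 1L]]), "[[:space:]]+")[[1L]]
    if (length(f) != dim + 1L) {
      stop("malformed row ", i, ": expected ", dim + 1L, " fields, got ",
           length(f))
    }
    toks[[i]] <- f[[1L]]
    m[i, ] <- as.numeric(f[-1L])
  }
  rownames(m) <- toks
  structure(list(dimension = dim, vectors = m), class = "EmbeddingTable")
}
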