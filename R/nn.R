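# Feed-forward pair classifier: two ReLU hidden layers of 800 and 200
# units over the concatenated entity vectors, sigmoid output, binary
# cross-entropy loss, Adam optimization.  Implemented with dense matrix
# algebra; training is deterministic given the seed.

#' Neural-network configuration for pair prediction
#'
#' Defaults follow the architecture this package evaluates: hidden
#' widths 800 and 200, ReLU activations, adaptive-moment gradient
#' descent at 1e-3, batches of 64, 20 epochs.
#'
#' @param hidden Integer vector of hidden-layer widths.
#' @param activation Hidden activation (only `"relu"` is implemented).
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param epochs Passes over the training records.
#' @param seed Integer seed (initialization and shuffling).
#' @return An `NNConfig` list.
#' @export
nn_config <- function(hidden = c(800L, 200L), activation = "relu",
                      learning_rate = 1e-3, batch_size = 64L,
                      epochs = 20L, seed = 1L) {
  activation <- match.arg(activation, "relu")
  stopifnot(all(hidden >= 1L), learning_rate > 0, batch_size >= 1L,
            epochs >= 1L)
  structure(list(hidden = as.integer(hidden), activation = activation,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "NNConfig")
}

#' Fit a feed-forward binary classifier
#'
#' @param X Numeric matrix of inputs (rows = records).
#' @param y 0/1 numeric vector of labels.
#' @param cfg An [nn_config()] object.
#' @return A fitted `pair_mlp` model.
#' @export
mlp_fit <- function(X, y, cfg = nn_config()) {
  stopifnot(is.matrix(X), nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) {
    stop("training data must contain both labels")
  }
  sizes <- c(ncol(X), cfg$hidden, 1L)
  L <- length(sizes) - 1L
  withr::with_seed(cfg$seed, {
    W <- lapply(seq_len(L), function(l) {
      matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
             nrow = sizes[l])
    })
    b <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1L]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    n <- nrow(X)
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        m <- length(idx)
        # forward
        A <- vector("list", L + 1L)
        A[[1L]] <- Xb
        for (l in seq_len(L)) {
          Z <- sweep(A[[l]] %*% W[[l]], 2L, b[[l]], `+`)
          A[[l + 1L]] <- if (l < L) pmax(Z, 0) else 1 / (1 + exp(-Z))
        }
        # backward (BCE + sigmoid collapses to p - y)
        delta <- (A[[L + 1L]] - yb) / m
        step <- step + 1L
        corr1 <- 1 - beta1^step
        corr2 <- 1 - beta2^step
        for (l in rev(seq_len(L))) {
          gW <- crossprod(A[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          W[[l]] <- W[[l]] - cfg$learning_rate * (mW[[l]] / corr1) /
            (sqrt(vW[[l]] / corr2) + eps)
          b[[l]] <- b[[l]] - cfg$learning_rate * (mb[[l]] / corr1) /
            (sqrt(vb[[l]] / corr2) + eps)
        }
      }
    }
  })
  structure(list(W = W, b = b, hidden = cfg$hidden, cfg = cfg),
            class = "pair_mlp")
}

#' @export
predict.pair_mlp <- function(object, newdata, ...) {
  A <- as.matrix(newdata)
  L <- length(object$W)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% object$W[[l]], 2L, object$b[[l]], `+`)
    A <- if (l < L) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  as.numeric(A)
}

#' Hidden-layer widths of a fitted model
#'
#' @param model A `pair_mlp`.
#' @return Integer vector of hidden widths, e.g. `c(800, 200)`.
#' @export
model_layers <- function(model) model$hidden

#' @export
print.pair_mlp <- function(x, ...) {
  cat("<pair_mlp> input ", nrow(x$W[[1L]]), " -> hidden ",
      paste(x$hidden, collapse = "/"), " -> sigmoid\n", sep = "")
  invisible(x)
}

#' Constructed two-cluster benchmark for the pair classifier
#'
#' Builds synthetic entity embeddings as two Gaussian clusters whose
#' means differ by `2 * shift` in every coordinate, labels same-cluster
#' pairs positive, and assembles a [build_pair_dataset()] over them.
#' Same-cluster membership is recoverable from the concatenated pair
#' vectors, so a correctly wired classifier reaches high test AUC;
#' permuting the train labels (`permute_train = TRUE`) destroys the
#' signal available to fitting while leaving test labels intact — the
#' leakage canary under which test AUC must return to chance.
#'
#' @param seed Integer seed.
#' @param n Number of entities (split evenly between clusters).
#' @param dim Embedding dimension.
#' @param shift Per-coordinate half-distance between cluster means.
#' @param permute_train Randomly permute the labels of the train
#'   split.
#' @return List with `table` (an `EmbeddingTable`) and `dataset` (a
#'   `PairDataset`).
#' @export
cluster_pair_benchmark <- function(seed, n = 80L, dim = 50L, shift = 0.3,
                                   permute_train = FALSE) {
  stopifnot(n %% 2L == 0L, n >= 4L)
  withr::with_seed(seed, {
    cl <- rep(c(0L, 1L), each = n / 2L)
    V <- matrix(stats::rnorm(n * dim), n) +
      outer(ifelse(cl == 0L, -shift, shift), rep(1, dim))
    rownames(V) <- sprintf("E%04d", seq_len(n))
    tab <- structure(list(dimension = as.integer(dim), vectors = V),
                     class = "EmbeddingTable")
    pr <- t(utils::combn(n, 2L))
    same <- cl[pr[, 1L]] == cl[pr[, 2L]]
    pos <- data.frame(entity_a = rownames(V)[pr[same, 1L]],
                      entity_b = rownames(V)[pr[same, 2L]],
                      stringsAsFactors = FALSE)
    d <- build_pair_dataset(pos, rownames(V), seed = seed)
    if (permute_train) {
      tr <- d$split == "train"
      d$label[tr] <- sample(d$label[tr])
    }
    list(table = tab, dataset = d)
  })
}

#' Train the pair network and score the test split
#'
#' The input of each record is the concatenation of the two entity
#' vectors.  Interactions are unordered, so every training pair is
#' presented in both orders, and at inference the scores of the two
#' orders are averaged; scores therefore lie in `[0, 1]` and are
#' symmetric in pair order.  Fitting reads only `train` records; the
#' returned scores cover the `test` records.
#'
#' @param t An `EmbeddingTable` covering every dataset entity.
#' @param d A `PairDataset` whose train split contains both labels.
#' @param cfg An [nn_config()] object.
#' @return A `ScoreSet` on the test records, attribute `scorer = "nn"`.
#' @export
nn_fit_and_score <- function(t, d, cfg = nn_config()) {
  tr <- d[d$split == "train", , drop = FALSE]
  te <- d[d$split == "test", , drop = FALSE]
  if (length(unique(tr$label)) < 2L) {
    stop("train split must contain both positive and negative pairs")
  }
  va <- get_vectors(t, tr$entity_a)
  vb <- get_vectors(t, tr$entity_b)
  Xtr <- rbind(cbind(va, vb), cbind(vb, va))
  ytr <- c(tr$label, tr$label)
  model <- mlp_fit(Xtr, ytr, cfg)
  wa <- get_vectors(t, te$entity_a)
  wb <- get_vectors(t, te$entity_b)
  s <- (predict(model, cbind(wa, wb)) + predict(model, cbind(wb, wa))) / 2
  structure(data.frame(entity_a = te$entity_a, entity_b = te$entity_b,
                       score = s, stringsAsFactors = FALSE),
            class = c("ScoreSet", "data.frame"), scorer = "nn",
            model = model)
}
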