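# ROC/AUC by the rank statistic (ties half-weighted), the Mann-Whitney
# U test, and model-vs-model comparison.  The AUC and U share a tie
# convention, so U / (n_a * n_b) is exactly the AUC of the merged
# sample labeled by origin.

align_scores_labels <- function(scores, labels) {
  if (inherits(scores, "ScoreSet")) {
    if (inherits(labels, "data.frame")) {
      key_s <- pair_key(scores$entity_a, scores$entity_b)
      key_l <- pair_key(labels$entity_a, labels$entity_b)
      m <- match(key_s, key_l)
      if (anyNA(m)) stop("scored pairs missing from the label set")
      list(scores = scores$score, labels = labels$label[m])
    } else {
      list(scores = scores$score, labels = labels)
    }
  } else {
    list(scores = as.numeric(scores), labels = labels)
  }
}

#' ROC curve and AUC from scores and binary labels
#'
#' The AUC is computed by the rank statistic with ties given half
#' credit: `AUC = (#\{s+ > s-\} + 0.5 #\{s+ = s-\}) / (n+ n-)`, i.e.
#' the probability that a random positive outscores a random negative.
#' The ROC is evaluated at every distinct score threshold and is
#' monotone from (0, 0) to (1, 1).
#'
#' @param scores Numeric scores or a `ScoreSet`.
#' @param labels 0/1 labels aligned with `scores`, or a `PairDataset`
#'   to join on the pair identity.
#' @return An `EvalResult`: list with `auc`, `roc` (data frame
#'   `threshold`, `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  al <- align_scores_labels(scores, labels)
  s <- al$scores
  y <- as.integer(al$labels)
  stopifnot(length(s) == length(y), all(y %in% c(0L, 1L)))
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both labels must be present to compute a ROC curve")
  }
  r <- rank(s)  # midranks: ties share credit
  auc <- (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(s), decreasing = TRUE)
  ord <- order(s, decreasing = TRUE)
  cum_tp <- cumsum(y[ord] == 1L)
  cum_fp <- cumsum(y[ord] == 0L)
  last <- cumsum(tabulate(match(s[ord], thr), nbins = length(thr)))
  roc <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, cum_fp[last] / n_neg),
                    tpr = c(0, cum_tp[last] / n_pos))
  structure(list(auc = auc, roc = roc, n_pos = n_pos, n_neg = n_neg),
            class = "EvalResult")
}

#' @export
print.EvalResult <- function(x, ...) {
  cat(sprintf("<EvalResult> AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Write an evaluation result to disk
#'
#' The ROC points go to a TSV (`threshold`, `fpr`, `tpr`); the summary
#' (AUC and counts) to a JSON file.
#'
#' @param res An `EvalResult`.
#' @param roc_path,summary_path Output file paths (`NULL` to skip one).
#' @return `res`, invisibly.
#' @export
write_eval_result <- function(res, roc_path = NULL, summary_path = NULL) {
  if (!is.null(roc_path)) {
    utils::write.table(res$roc, roc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(summary_path)) {
    jsonlite::write_json(list(auc = res$auc, n_pos = res$n_pos,
                              n_neg = res$n_neg),
                         summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}

#' Two-sided Mann-Whitney U test
#'
#' `U` counts, over all cross pairs, the times a value of `a` exceeds a
#' value of `b` (ties half-weighted).  When `n_a * n_b <= 400` and
#' there are no ties the exact null distribution of U is used;
#' otherwise a normal approximation with tie and continuity correction.
#'
#' @param a,b Numeric samples.
#' @return List with `U`, `p_value`, `method`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  na_ <- length(a)
  nb_ <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na_)]) - na_ * (na_ + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  if (na_ * nb_ <= 400 && !ties) {
    p <- 2 * min(stats::pwilcox(U, na_, nb_),
                 1 - stats::pwilcox(U - 1, na_, nb_))
    p <- min(1, p)
    method <- "exact"
  } else {
    N <- na_ + nb_
    tab <- table(c(a, b))
    tie_term <- sum(tab^3 - tab) / (N * (N - 1))
    sigma2 <- na_ * nb_ / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(U - na_ * nb_ / 2) - 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-z)
    }
    method <- "normal-approximation"
  }
  list(U = U, p_value = min(1, p), method = method)
}

#' Compare two scorers on the same pair universe
#'
#' Two interpretations of a model-vs-model significance test are
#' offered, and the result records which was used.
#' `"mwu-on-positive-scores"` applies the Mann-Whitney U test to the
#' score distributions that the two models assign to the positive
#' pairs.  `"paired-bootstrap"` resamples the pairs (within label
#' strata, `n_resamples` times) and reports the two-sided bootstrap p
#' for a nonzero AUC difference.  Deterministic given `seed`.
#'
#' @param scores_a,scores_b `ScoreSet`s (or numeric vectors) over the
#'   same pairs.
#' @param labels 0/1 labels aligned with the scores, or a
#'   `PairDataset`.
#' @param method Comparison method.
#' @param seed Integer seed (bootstrap only).
#' @param n_resamples Bootstrap resamples.
#' @return A `ComparisonResult`: list with `auc_a`, `auc_b`, `delta`,
#'   `p_value`, `method`, `n_resamples`.
#' @export
compare_models <- function(scores_a, scores_b, labels,
                           method = c("paired-bootstrap",
                                      "mwu-on-positive-scores"),
                           seed = 1L, n_resamples = 1000L) {
  method <- match.arg(method)
  if (inherits(scores_a, "ScoreSet") && inherits(scores_b, "ScoreSet")) {
    key_a <- pair_key(scores_a$entity_a, scores_a$entity_b)
    key_b <- pair_key(scores_b$entity_a, scores_b$entity_b)
    m <- match(key_a, key_b)
    if (anyNA(m) || length(key_a) != length(key_b)) {
      stop("the two score sets must cover the same pairs")
    }
    scores_b <- scores_b[m, , drop = FALSE]
  }
  al_a <- align_scores_labels(scores_a, labels)
  al_b <- align_scores_labels(scores_b, labels)
  sa <- al_a$scores
  sb <- al_b$scores
  y <- al_a$labels
  stopifnot(length(sa) == length(sb))
  auc_a <- roc_auc(sa, y)$auc
  auc_b <- roc_auc(sb, y)$auc
  if (method == "mwu-on-positive-scores") {
    mw <- mann_whitney(sa[y == 1L], sb[y == 1L])
    res <- list(auc_a = auc_a, auc_b = auc_b, delta = auc_a - auc_b,
                p_value = mw$p_value, method = method, n_resamples = NA_integer_)
  } else {
    pos <- which(y == 1L)
    neg <- which(y == 0L)
    deltas <- withr::with_seed(seed, {
      vapply(seq_len(n_resamples), function(i) {
        idx <- c(pos[sample.int(length(pos), replace = TRUE)],
                 neg[sample.int(length(neg), replace = TRUE)])
        roc_auc(sa[idx], y[idx])$auc - roc_auc(sb[idx], y[idx])$auc
      }, numeric(1))
    })
    p <- 2 * min((1 + sum(deltas <= 0)) / (n_resamples + 1),
                 (1 + sum(deltas >= 0)) / (n_resamples + 1))
    res <- list(auc_a = auc_a, auc_b = auc_b, delta = auc_a - auc_b,
                p_value = min(1, p), method = method,
                n_resamples = as.integer(n_resamples),
                bootstrap_mean_delta = mean(deltas))
  }
  structure(res, class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf(
    "<ComparisonResult> AUC %.4f vs %.4f (delta %+.4f), p = %.4g [%s]\n",
    x$auc_a, x$auc_b, x$delta, x$p_value, x$method))
  invisible(x)
}
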