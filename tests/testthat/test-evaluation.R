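# Rank-based ROC/AUC, Mann-Whitney U, and model comparison.

test_that("degenerate score patterns hit the documented AUC values", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(2, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both labels")
})

test_that("AUC equals the brute-force pairwise count on random instances", {
  withr::with_seed(21, {
    for (i in 1:50) {
      n <- sample(10:200, 1)
      y <- rbinom(n, 1, 0.4)
      if (length(unique(y)) < 2) next
      s <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
      expect_equal(roc_auc(s, y)$auc, brute_auc(s, y), tolerance = 1e-12)
    }
  })
})

test_that("ROC runs from (0,0) to (1,1) and is monotone", {
  withr::with_seed(3, {
    s <- rnorm(60)
    y <- rbinom(60, 1, 0.5)
    roc <- roc_auc(s, y)$roc
    expect_equal(roc$fpr[1], 0)
    expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1)
    expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$tpr) >= 0))
  })
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(4, {
    s <- rnorm(100)
    y <- rbinom(100, 1, 0.5)
    expect_equal(roc_auc(s, y)$auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  })
})

test_that("AUC is invariant under strictly increasing transforms", {
  withr::with_seed(6, {
    s <- rnorm(80)
    y <- rbinom(80, 1, 0.5)
    a <- roc_auc(s, y)$auc
    expect_equal(roc_auc(exp(s), y)$auc, a)
    expect_equal(roc_auc(rank(s), y)$auc, a)
    expect_equal(roc_auc(-s, y)$auc, 1 - a)  # no ties in rnorm draws
  })
})

test_that("Mann-Whitney exact path reproduces hand-enumerated cases", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 2 / choose(4, 2), tolerance = 1e-12)
  # identical multisets: U = n^2/2, p about 1 (tie path)
  r2 <- mann_whitney(c(1, 2), c(1, 2))
  expect_equal(r2$U, 2)
  expect_equal(r2$p_value, 1)
})

test_that("Mann-Whitney agrees with wilcox.test on both code paths", {
  withr::with_seed(31, {
    for (i in 1:20) {
      na_ <- sample(3:15, 1)
      nb_ <- sample(3:15, 1)
      a <- rnorm(na_)
      b <- rnorm(nb_) + runif(1, -1, 1)
      r <- mann_whitney(a, b)
      w <- wilcox.test(a, b, exact = na_ * nb_ <= 400, correct = TRUE)
      expect_equal(r$U, unname(w$statistic))
      expect_equal(r$p_value, w$p.value, tolerance = 1e-10)
    }
    # tie-heavy large samples exercise the normal approximation
    a <- sample(1:5, 40, replace = TRUE)
    b <- sample(2:6, 35, replace = TRUE)
    r <- mann_whitney(a, b)
    expect_equal(r$method, "normal-approximation")
    w <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(r$p_value, w$p.value, tolerance = 1e-10)
  })
})

test_that("U/(na*nb) equals the AUC of the merged labeled sample", {
  withr::with_seed(41, {
    for (i in 1:100) {
      na_ <- sample(2:25, 1)
      nb_ <- sample(2:25, 1)
      a <- sample(1:10, na_, replace = TRUE)  # ties on purpose
      b <- sample(1:10, nb_, replace = TRUE)
      U <- mann_whitney(a, b)$U
      auc <- roc_auc(c(a, b), c(rep(1, na_), rep(0, nb_)))$auc
      expect_identical(U / (na_ * nb_), auc)
    }
  })
})

test_that("self-comparison gives zero delta and p of 1", {
  withr::with_seed(2, {
    s <- rnorm(60)
    y <- rbinom(60, 1, 0.5)
    r <- compare_models(s, s, y, method = "paired-bootstrap", seed = 1)
    expect_equal(r$delta, 0)
    expect_equal(r$p_value, 1)
  })
})

test_that("a strong scorer beats a random one decisively", {
  ps <- vapply(1:5, function(sd) {
    withr::with_seed(sd, {
      y <- rbinom(200, 1, 0.5)
      strong <- y + rnorm(200, sd = 0.4)
      random <- rnorm(200)
      compare_models(strong, random, y, method = "paired-bootstrap",
                     seed = sd)$p_value
    })
  }, numeric(1))
  expect_true(all(ps < 0.01))
})

test_that("bootstrap mean delta tracks the point-estimate delta", {
  withr::with_seed(17, {
    y <- rbinom(300, 1, 0.5)
    sa <- y + rnorm(300)
    sb <- y + rnorm(300, sd = 2)
    r <- compare_models(sa, sb, y, seed = 5)
    expect_lt(abs(r$bootstrap_mean_delta - r$delta), 0.01)
  })
})

test_that("the positive-score Mann-Whitney comparison mode is reported", {
  withr::with_seed(23, {
    y <- rbinom(100, 1, 0.5)
    sa <- y + rnorm(100, sd = 0.5)
    sb <- rnorm(100)
    r <- compare_models(sa, sb, y, method = "mwu-on-positive-scores")
    expect_equal(r$method, "mwu-on-positive-scores")
    expect_true(r$p_value >= 0 && r$p_value <= 1)
  })
})

test_that("score sets over different pairs are rejected", {
  mk <- function(ents) {
    structure(data.frame(entity_a = ents[1], entity_b = ents[2], score = 0.5),
              class = c("ScoreSet", "data.frame"), scorer = "cosine")
  }
  expect_error(compare_models(mk(c("a", "b")), mk(c("a", "c")), c(1)),
               "same pairs")
})
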