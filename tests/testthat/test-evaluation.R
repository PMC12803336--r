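test_that("Spearman rho reproduces rank-based expectations", {
  x <- c(0.1, 0.4, 2, 7)
  expect_equal(spearman_rho(x, exp(x)), 1)          # strictly monotone
  expect_equal(spearman_rho(x, rev(x)), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  # agrees with the base implementation, including ties
  set.seed(20)
  a <- sample(1:10, 50, replace = TRUE)
  b <- a + rnorm(50)
  expect_equal(spearman_rho(a, b), cor(a, b, method = "spearman"))
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(21)
  x <- runif(100)
  y <- x^2 + rnorm(100, sd = 0.2)
  r <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(3 * x), y), r)
  expect_equal(spearman_rho(x, qlogis(plogis(y))), r, tolerance = 1e-12)
})

test_that("AUC equals the pairwise-comparison probability with half-credit ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(0.5, 0.1, 0.5, 0.1), 0.23), 0.75)
  # perfect separation
  expect_equal(roc_auc(c(5, 4, 1, 0), c(0.9, 0.8, 0.1, 0.1), 0.23), 1)
  # energy orientation: perfectly separating lower-is-better score
  expect_equal(roc_auc(c(-5, -4, 1, 0), c(0.9, 0.8, 0.1, 0.1), 0.23,
                       lower_is_better = TRUE), 1)
  # brute force over all positive-negative pairs
  set.seed(22)
  dq <- runif(80)
  sc <- dq + rnorm(80, sd = 0.3)
  pos <- which(dq >= 0.23); neg <- which(dq < 0.23)
  wins <- 0
  for (i in pos) for (j in neg) {
    wins <- wins + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
  }
  expect_equal(roc_auc(sc, dq, 0.23), wins / (length(pos) * length(neg)))
  # agrees with an independent ROC implementation
  expect_equal(roc_auc(sc, dq, 0.23),
               as.numeric(pROC::auc(pROC::roc(dq >= 0.23, sc, quiet = TRUE,
                                              direction = "<"))))
  expect_error(roc_auc(1:4, c(0.9, 0.8, 0.9, 0.8), 0.23), "classes")
})

test_that("the AUC curve is 1 for a perfect score and ~0.5 for noise", {
  set.seed(23)
  set <- data.frame(model_id = 1:4000, dockq = runif(4000))
  set$perfect <- set$dockq
  set$noise <- rnorm(4000)
  expect_true(all(auc_curve(set, "perfect")$auc == 1))
  expect_true(all(abs(auc_curve(set, "noise")$auc - 0.5) < 0.05))
})

test_that("hit rate counts targets with a positive in the top R", {
  mk <- function(dq, sc) data.frame(model_id = seq_along(dq), dockq = dq, score = sc)
  sets <- list(
    mk(c(0.9, 0.1, 0.1), c(3, 2, 1)),   # positive at rank 1
    mk(c(0.1, 0.9, 0.1), c(3, 2, 1)),   # positive at rank 2
    mk(c(0.1, 0.1, 0.1), c(3, 2, 1))    # no positive at all
  )
  h <- hit_rate(sets, "score", R_max = 3)
  expect_equal(h$hit_rate, c(1 / 3, 2 / 3, 2 / 3))
  expect_true(all(diff(h$hit_rate) >= 0))
})

test_that("effective hit rate matches exhaustive enumeration on a tiny set", {
  set <- data.frame(model_id = 1:6,
                    dockq = c(0.9, 0.1, 0.1, 0.1, 0.1, 0.1),
                    score = c(1, 6, 5, 4, 3, 2))  # positive ranked last
  # exact: over all C(6,4) subsets, P(positive within top R of the 4)
  combos <- combn(6, 4)
  exact <- vapply(1:4, function(R) {
    mean(apply(combos, 2, function(idx) {
      ord <- idx[order(-set$score[idx])]
      any(set$dockq[ord[seq_len(min(R, 4))]] >= 0.23)
    }))
  }, numeric(1))
  got <- effective_hit_rate(set, "score", Nm = 4, Ns = 4000, R_max = 4, seed = 31)
  expect_equal(got$hit_rate, exact, tolerance = 0.05)
  # all-positive set saturates at 1
  allpos <- data.frame(model_id = 1:5, dockq = runif(5, 0.5, 1), score = 1:5)
  expect_true(all(effective_hit_rate(allpos, "score", Nm = 3, Ns = 50,
                                     R_max = 5, seed = 1)$hit_rate == 1))
})

test_that("negative dominance counts negatives strictly outranking all positives", {
  set <- data.frame(model_id = 1:6,
                    dockq = c(0.9, 0.5, 0.1, 0.1, 0.1, 0.1),
                    score = c(4, 3, 6, 5, 2, 1))
  # two negatives (scores 6, 5) beat the best positive (4)
  expect_equal(negative_dominance_mu(set, "score"), 2 / 6)
  # all positives first
  first <- data.frame(model_id = 1:4, dockq = c(0.9, 0.5, 0.1, 0.1),
                      score = c(9, 8, 2, 1))
  expect_equal(negative_dominance_mu(first, "score"), 0)
  # all negatives dominate in a balanced set
  dom <- data.frame(model_id = 1:4, dockq = c(0.9, 0.5, 0.1, 0.1),
                    score = c(2, 1, 9, 8))
  expect_equal(negative_dominance_mu(dom, "score"), 0.5)
  # energy orientation flips the comparison
  expect_equal(negative_dominance_mu(dom, "score", lower_is_better = TRUE), 0)
})

test_that("evaluate_scores aggregates the individual statistics", {
  set.seed(24)
  set <- make_score_dockq_dataset(500, rho_target = -0.6, seed = 3)
  summ <- evaluate_scores(set, "score", lower_is_better = TRUE)
  expect_equal(summ$rho, spearman_rho(set$dockq, set$score))
  expect_equal(summ$auc, roc_auc(set$score, set$dockq, 0.23, lower_is_better = TRUE))
  expect_equal(summ$mu, negative_dominance_mu(set, "score", lower_is_better = TRUE))
})
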