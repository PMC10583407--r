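test_that("ROC handles the canonical hand cases", {
  r <- roc_analysis(c(0.1, 0.4, 0.35, 0.8),
                    factor(c("neg", "neg", "pos", "pos"), levels = c("pos", "neg")))
  expect_equal(r$auc, 0.75)  # 3 of 4 pos/neg pairs concordant

  sep <- roc_analysis(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 2, 2))
  expect_equal(sep$auc, 1)
  expect_equal(sep$sens_at_best, 1)
  expect_equal(sep$spec_at_best, 1)

  tied <- roc_analysis(rep(0.5, 10), rep(c(1, 2), 5))
  expect_equal(tied$auc, 0.5)

  expect_error(roc_analysis(1:3, rep(1, 3)), "classes")
})

test_that("concordance AUC equals the trapezoidal area on random instances", {
  withr::with_seed(6, {
    for (rep_i in 1:200) {
      n <- sample(4:20, 1)
      lab <- c(1, 2, sample(1:2, n - 2, replace = TRUE))
      scores <- round(rnorm(n), sample(0:2, 1))  # coarse rounding forces ties
      r <- roc_analysis(scores, lab)
      pts <- r$points[order(1 - r$points$specificity, r$points$sensitivity), ]
      fpr <- 1 - pts$specificity
      trap <- sum(diff(fpr) * (head(pts$sensitivity, -1) + pts$sensitivity[-1]) / 2)
      expect_lt(abs(r$auc - trap), 1e-12)
    }
  })
})

test_that("the reported threshold maximizes sensitivity plus specificity", {
  withr::with_seed(9, {
    for (rep_i in 1:50) {
      n <- sample(6:15, 1)
      lab <- c(1, 2, sample(1:2, n - 2, replace = TRUE))
      scores <- round(runif(n), 1)
      r <- roc_analysis(scores, lab)
      pos <- scores[lab == 1]
      neg <- scores[lab == 2]
      best <- max(vapply(r$points$threshold,
                         function(t) mean(pos >= t) + mean(neg < t), numeric(1)))
      expect_equal(r$sens_at_best + r$spec_at_best, best, tolerance = 1e-12)
      # tie-break: no equal-J threshold has higher sensitivity
      js <- r$points$sensitivity + r$points$specificity
      ties <- which(abs(js - best) < 1e-12)
      expect_gte(r$sens_at_best, max(r$points$sensitivity[ties]) - 1e-12)
    }
  })
})

test_that("Fisher's exact test equals full enumeration over small tables", {
  r <- confusion_and_association(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(r$table[1, 1] + r$table[2, 2], 4)
  expect_equal(r$fisher_p, 1 / 3, tolerance = 1e-9)  # [[2,0],[0,2]]

  # every 2x2 table with total <= 10
  for (a in 0:4) for (b in 0:3) for (c_ in 0:3) for (d in 0:4) {
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    if (sum(tab) == 0 || sum(tab) > 10) next
    expect_equal(stats::fisher.test(tab)$p.value, fisher_enumerate(tab),
                 tolerance = 1e-7)
  }
})

test_that("Yule's Q follows the cross-product formula and flags degeneracy", {
  actual <- rep(c(1, 0), c(41, 14))
  predicted <- c(rep(1, 36), rep(0, 5), rep(1, 1), rep(0, 13))
  r <- confusion_and_association(predicted, actual)
  expect_equal(unname(r$table[1, ]), c(36, 5))
  expect_equal(unname(r$table[2, ]), c(1, 13))
  expect_equal(r$yule_q, 463 / 473, tolerance = 1e-12)

  indep <- confusion_and_association(rep(c(1, 0), 4), rep(c(1, 1, 0, 0), 2))
  expect_equal(indep$yule_q, 0)

  expect_warning(deg <- confusion_and_association(c(1, 1, 1, 1), c(1, 1, 0, 0)),
                 "undefined")
  expect_false(deg$q_defined)
  expect_true(is.na(deg$yule_q))
})

test_that("DeLong test is degenerate-safe and matches an independent implementation", {
  withr::with_seed(31, {
    lab <- rep(c(1, 2), c(12, 8))
    s_a <- rnorm(20) + (lab == 1)
    s_b <- 0.5 * s_a + rnorm(20, sd = 0.5)
  })
  expect_warning(same <- delong_test(s_a, s_a, lab), "Zero variance")
  expect_equal(same$p, 1)
  expect_equal(same$auc_a, same$auc_b)

  dl <- delong_test(s_a, s_b, lab)
  skip_if_not_installed("pROC")
  ra <- pROC::roc(lab, s_a, levels = c(2, 1), direction = "<", quiet = TRUE)
  rb <- pROC::roc(lab, s_b, levels = c(2, 1), direction = "<", quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(dl$p, ref$p.value, tolerance = 1e-9)
  expect_equal(unname(dl$auc_a), as.numeric(ra$auc), tolerance = 1e-12)

  # single-AUC variance against the same reference
  expect_equal(delong_auc_variance(s_a, lab), as.numeric(pROC::var(ra)),
               tolerance = 1e-9)
})

test_that("DeLong variance matches a manual placement-value computation", {
  scores <- c(0.9, 0.7, 0.4, 0.8, 0.3, 0.2)
  lab <- c(1, 1, 1, 2, 2, 2)
  pos <- scores[1:3]
  neg <- scores[4:6]
  psi <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  manual <- stats::var(v10) / 3 + stats::var(v01) / 3
  expect_equal(delong_auc_variance(scores, lab), manual, tolerance = 1e-15)
})

test_that("Holm adjustment reproduces the step-down rule", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(0.3, 3)), rep(min(3 * 0.3, 1), 3))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
  # monotone after sorting by raw p
  withr::with_seed(2, p <- runif(8))
  adj <- holm_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("Brunner-Munzel recovers the relative effect", {
  a <- c(1, 3, 2, 4, 6, 5)
  r1 <- brunner_munzel(a, a)
  expect_equal(r1$relative_effect, 0.5)

  # complete separation: the relative effect is defined, the
  # studentized statistic is not (zero rank variance)
  expect_warning(r2 <- brunner_munzel(c(1, 2), c(3, 4)), "tied")
  expect_equal(r2$relative_effect, 1)

  expect_warning(r3 <- brunner_munzel(rep(1, 4), rep(1, 5)), "tied")
  expect_true(r3$flagged)

  # Monte-Carlo oracle for P(A < B) + 0.5 P(A = B)
  withr::with_seed(44, {
    x <- rgamma(25, 2)
    y <- rnorm(18, mean = 1.2)
    r <- brunner_munzel(x, y)
    xs <- sample(x, 1e5, replace = TRUE)
    ys <- sample(y, 1e5, replace = TRUE)
    mc <- mean(xs < ys) + 0.5 * mean(xs == ys)
  })
  expect_lt(abs(r$relative_effect - mc), 0.01)
  expect_error(brunner_munzel(1, c(1, 2)), "at least 2")
})
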