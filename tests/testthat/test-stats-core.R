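test_that("wilcoxon rank sum matches exact enumeration and symmetry", {
  # U = 0; two-sided exact p = 2 / C(6,3) = 0.1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  # identical samples: all ranks tied, p = 1
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  # large shifted samples: approximation path equals independent transcription
  set.seed(11)
  x <- rnorm(40); y <- rnorm(45, mean = 0.6)
  got <- wilcoxon_rank_sum(x, y)
  expect_equal(got$method, "wilcoxon_normal")
  expect_equal(got$p_value, oracle_wilcoxon_normal(x, y), tolerance = 1e-6)
  # with ties
  xt <- round(rnorm(30), 1); yt <- round(rnorm(30, 0.4), 1)
  expect_equal(wilcoxon_rank_sum(xt, yt)$p_value,
               oracle_wilcoxon_normal(xt, yt), tolerance = 1e-6)
})

test_that("wilcoxon exact and approximate paths agree near the switch", {
  # enumerate every attainable U at 6 + 6 tie-free observations; without a
  # continuity correction the exact and normal-approximation p-values agree
  # to at most ~0.07 absolute (and ~0.02 in the median), which is the
  # attainable bound at this sample size
  exact_p <- vapply(0:36, function(U) {
    min(1, if (U > 18) 2 * pwilcox(U - 1, 6, 6, lower.tail = FALSE)
           else 2 * pwilcox(U, 6, 6))
  }, numeric(1))
  approx_p <- vapply(0:36, function(U) {
    2 * pnorm(-abs((U - 18) / sqrt(6 * 6 * 13 / 12)))
  }, numeric(1))
  expect_lt(max(abs(exact_p - approx_p)), 0.07)
  expect_lt(median(abs(exact_p - approx_p)), 0.03)
  # the implemented switch reproduces both columns
  set.seed(21)
  for (rep in 1:10) {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    got <- wilcoxon_rank_sum(x, y)
    expect_equal(got$method, "wilcoxon_exact")
    expect_equal(got$p_value, exact_p[got$statistic + 1], tolerance = 1e-12)
    xl <- rnorm(7); yl <- rnorm(6, 0.5)
    expect_equal(wilcoxon_rank_sum(xl, yl)$method, "wilcoxon_normal")
  }
})

test_that("welch t matches hand formula and conventions", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # near-degenerate separation
  expect_lt(welch_t(c(0, 0, 0, 0), c(1, 1, 1, 1.0001))$p_value, 1e-6)
  # hand computation
  x <- c(1.1, 2.3, 0.7, 1.9); y <- c(3.2, 4.1, 2.8)
  se2 <- var(x) / 4 + var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 3)^2 / 2)
  got <- welch_t(x, y)
  expect_equal(got$statistic, t_hand, tolerance = 1e-12)
  expect_equal(got$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  # antisymmetry
  swapped <- welch_t(y, x)
  expect_equal(swapped$statistic, -got$statistic)
  expect_equal(swapped$p_value, got$p_value)
  # zero-variance convention
  expect_equal(welch_t(c(1, 1), c(1, 1))$p_value, 1)
  expect_equal(welch_t(c(1, 1), c(2, 2))$p_value, 0)
})

test_that("p-value adjustment reproduces hand calculations", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.5, "BH"), 0.5)
  expect_equal(adjust_pvalues(0.5, "bonferroni"), 0.5)
  expect_equal(adjust_pvalues(c(0.04, 0.5), "bonferroni"), c(0.08, 1.0))
  # BH step-up by hand on an unsorted vector
  p <- c(0.30, 0.01, 0.04, 0.90)
  m <- 4
  sorted <- sort(p)
  adj_sorted <- rev(cummin(rev(sorted * m / seq_len(m))))
  expect_equal(sort(adjust_pvalues(p, "BH")), pmin(1, adj_sorted))
  # monotone: order preserved, never above 1
  set.seed(5)
  q <- runif(50)
  a <- adjust_pvalues(q, "BH")
  expect_true(all(a <= 1))
  expect_equal(order(q), order(q)[order(a[order(q)])]) # BH preserves p-order
  expect_error(adjust_pvalues(c(0.2, 1.2)), "0, 1")
})

test_that("wilson interval matches the closed form and boundaries", {
  got <- wilson_ci(50, 100, 0.95)
  expect_equal(unname(got), c(0.4038315, 0.5961685), tolerance = 1e-3)
  expect_equal(unname(wilson_ci(0, 10, 0.95)["lo"]), 0)
  expect_equal(unname(wilson_ci(10, 10, 0.95)["hi"]), 1)
  expect_error(wilson_ci(5, 0), ">= 1")
})

test_that("wilson interval approximately covers at the nominal level", {
  set.seed(77)
  p_true <- 0.3; n <- 40
  cover <- replicate(2000, {
    k <- rbinom(1, n, p_true)
    ci <- wilson_ci(k, n, 0.95)
    ci["lo"] <= p_true && p_true <= ci["hi"]
  })
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.98)
})

test_that("roc_auc equals pairwise concordance and handles edge cases", {
  expect_equal(roc_auc(c(0.9, 0.8), c(0.1, 0.2))$auc, 1.0)
  expect_equal(roc_auc(c(2, 4), c(1, 3))$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  set.seed(9)
  for (rep in 1:25) {
    n1 <- sample(2:20, 1); n2 <- sample(2:20, 1)
    pos <- sample(round(rnorm(n1, 0.3), 1))
    neg <- sample(round(rnorm(n2), 1))
    expect_equal(roc_auc(pos, neg)$auc, oracle_auc(pos, neg))
  }
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  pos <- rnorm(30, 1); neg <- rnorm(25)
  got <- roc_auc(pos, neg)
  ref <- pROC::roc(response = rep(c(1, 0), c(30, 25)),
                   predictor = c(pos, neg), quiet = TRUE, direction = "<")
  expect_equal(got$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("youden threshold sensitivity/specificity are coherent", {
  set.seed(31)
  pos <- rnorm(40, 1.5); neg <- rnorm(40)
  r <- roc_auc(pos, neg)
  expect_equal(r$sensitivity, mean(pos >= r$threshold))
  expect_equal(r$specificity, mean(neg < r$threshold))
  expect_true(r$sens_ci["lo"] <= r$sensitivity && r$sensitivity <= r$sens_ci["hi"])
  expect_true(r$spec_ci["lo"] <= r$specificity && r$specificity <= r$spec_ci["hi"])
  expect_equal(r$threshold_rule, "youden")
})

test_that("hypergeometric enrichment matches combinatorial hand values", {
  u <- sprintf("u%02d", 1:10)
  res <- hypergeometric_enrichment(u[1:5], u[1:5], u)
  expect_equal(res$p_value, 1 / choose(10, 5))
  expect_equal(res$statistic, 5)
  # zero overlap: exact tail sum by enumeration
  res0 <- hypergeometric_enrichment(u[1:2], u[3:5], u)
  expect_equal(res0$p_value, 1) # P(X >= 0) is certain
  # list = universe makes overlap certain
  expect_equal(hypergeometric_enrichment(u, u[1:4], u)$p_value, 1)
  # a genuinely partial overlap, checked against dhyper enumeration
  res2 <- hypergeometric_enrichment(u[1:4], u[3:7], u)
  k <- length(intersect(u[1:4], u[3:7]))
  expect_equal(res2$p_value, sum(dhyper(k:4, 5, 5, 4)))
  expect_error(hypergeometric_enrichment(c("zz"), u[1:2], u), "outside")
})
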