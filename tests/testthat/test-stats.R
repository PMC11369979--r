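test_that("Mann-Whitney handles separation, ties and the AUC identity", {
  # fully separated 3 vs 3: exact two-sided p = 2/20
  res <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1, tolerance = 1e-12)

  # identical constant samples: tie-degenerate
  res2 <- mann_whitney(rep(4, 6), rep(4, 8))
  expect_equal(res2$U, 6 * 8 / 2)
  expect_equal(res2$p, 1)

  # U/(n1 n2) equals the trapezoidal AUC on the same data
  set.seed(12)
  for (i in 1:50) {
    x <- sample(0:9, 12, replace = TRUE)
    y <- sample(0:9, 15, replace = TRUE)
    mw <- mann_whitney(x, y)
    rc <- roc_curve(c(x, y), c(rep("PD", 12), rep("HC", 15)),
                    "higher_is_positive")
    expect_equal(mw$U / (12 * 15), auc_trapezoid(rc), tolerance = 1e-12)
  }

  # agrees with the reference implementation's statistic
  set.seed(3)
  x <- rnorm(25); y <- rnorm(30, 0.4)
  expect_equal(mann_whitney(x, y)$U,
               unname(stats::wilcox.test(x, y)$statistic))
  expect_equal(mann_whitney(x, y)$p,
               stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-10)
  expect_error(mann_whitney(numeric(0), y), "nonempty")
})

test_that("pooled t-test works from summaries and matches t.test on samples", {
  # reported age summaries: PD 65.00 (9.29) n=82 vs HC 65.51 (6.57) n=107
  res <- t_test_pooled(c(65.00, 9.29, 82), c(65.51, 6.57, 107), summary = TRUE)
  expect_equal(res$p, 0.656, tolerance = 0.02)

  set.seed(8)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  ours <- t_test_pooled(x, y)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)

  expect_equal(t_test_pooled(x, x)$t, 0)
  expect_error(t_test_pooled(c(1, 0, 5), c(2, 0, 5), summary = TRUE),
               "degenerate")
})

test_that("2x2 chi-square reproduces the reported sex-ratio comparison", {
  # 56/26 male/female in PD vs 51/56 in HC
  res <- chi_square_2x2(56, 26, 51, 56)
  expect_equal(res$chi2, 8.05, tolerance = 0.01)
  expect_lt(res$p, 0.006); expect_gt(res$p, 0.004)

  prop <- chi_square_2x2(10, 10, 20, 20)
  expect_equal(prop$chi2, 0, tolerance = 1e-12)
  expect_equal(prop$p, 1)

  # transposition invariance
  expect_equal(chi_square_2x2(56, 26, 51, 56)$chi2,
               chi_square_2x2(56, 51, 26, 56)$chi2, tolerance = 1e-12)
  expect_error(chi_square_2x2(0, 0, 3, 4), "marginal")
})

test_that("Spearman correlation: monotone extremes, ties, and transforms", {
  x <- c(1, 3, 5, 9, 11)
  expect_equal(spearman_corr(x, x^3)$coefficient, 1)
  expect_equal(spearman_corr(x, -x)$coefficient, -1)

  set.seed(9)
  xt <- sample(1:5, 20, replace = TRUE)
  yt <- xt + sample(0:2, 20, replace = TRUE)
  ours <- spearman_corr(xt, yt)
  expect_equal(ours$coefficient, cor(xt, yt, method = "spearman"),
               tolerance = 1e-12)
  # invariant to strictly monotone transforms
  expect_equal(spearman_corr(exp(xt), yt^3)$coefficient, ours$coefficient,
               tolerance = 1e-12)
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
})

test_that("Kendall tau-b equals the direct pair-count oracle", {
  expect_equal(kendall_tau_b(1:6, (1:6)^2)$coefficient, 1)
  set.seed(14)
  for (i in 1:30) {
    x <- sample(1:4, 8, replace = TRUE)
    y <- sample(1:4, 8, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau_b(x, y)$coefficient, kendall_bruteforce(x, y),
                 tolerance = 1e-12)
    expect_equal(kendall_tau_b(x, y)$coefficient,
                 kendall_tau_b(y, x)$coefficient, tolerance = 1e-12)
  }
  expect_error(kendall_tau_b(rep(2, 6), 1:6), "all-tied")
})

test_that("Spearman and Kendall agree in sign on monotone-coupled data", {
  set.seed(15)
  x <- rnorm(40); y <- -x + rnorm(40, 0, 0.3)
  expect_lt(spearman_corr(x, y)$coefficient, 0)
  expect_lt(kendall_tau_b(x, y)$coefficient, 0)
})

test_that("Bonferroni adjustment and significance flags", {
  expect_equal(bonferroni_alpha(0.05, 40), 0.00125)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.01, 10), 0.001)
  expect_error(bonferroni_alpha(0.05, 0), "m must be")
  expect_error(bonferroni_alpha(1.2, 4), "alpha")

  set.seed(16)
  x <- rnorm(50); y <- x + rnorm(50, 0, 0.5)
  strong <- spearman_corr(x, y, alpha = 0.05, m = 40)
  expect_true(strong$significant_after_bonferroni)
  expect_equal(strong$adjusted_alpha, 0.00125)
})

test_that("Mann-Whitney type-I error is near nominal under the null", {
  set.seed(17)
  rej <- mean(replicate(400, {
    mann_whitney(rnorm(30), rnorm(30))$p < 0.05
  }))
  expect_gt(rej, 0.02); expect_lt(rej, 0.08)
})
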