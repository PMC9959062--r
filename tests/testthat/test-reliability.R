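test_that("ICC(1,1) matches a from-scratch ANOVA oracle", {
  x <- rbind(c(7, 9), c(10, 13), c(8, 4), c(6, 8))
  res <- icc_oneway_single(x)
  # independent oracle: one-way ANOVA via stats::aov on the long layout
  long <- data.frame(y = as.vector(x),
                     subj = factor(rep(seq_len(nrow(x)), ncol(x))))
  ms <- summary(stats::aov(y ~ subj, data = long))[[1]][["Mean Sq"]]
  k <- ncol(x)
  icc_oracle <- (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
  expect_equal(res$icc, icc_oracle, tolerance = 1e-12)
  expect_equal(res$msb, ms[1], tolerance = 1e-12)
  expect_equal(res$msw, ms[2], tolerance = 1e-12)
  expect_true(res$ci_low <= res$icc && res$icc <= res$ci_high)
})

test_that("ICC limiting cases and degeneracy", {
  # raters identical per subject, subjects differ -> exactly 1
  x <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(icc_oneway_single(x)$icc, 1)
  # no between-subject variance, noisy raters -> non-positive
  set.seed(2)
  y <- matrix(rnorm(40), 20, 2)
  expect_lte(icc_oneway_single(y)$icc, 0.2)
  set.seed(4)
  y2 <- cbind(rep(5, 12), rep(5, 12) + rnorm(12))
  expect_lte(icc_oneway_single(y2)$icc, 0)
  expect_error(icc_oneway_single(matrix(3, 4, 2)), "degenerate")
  expect_error(icc_oneway_single(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("ICC is invariant to location shifts and positive scaling", {
  set.seed(8)
  x <- matrix(rnorm(40, sd = 2), 20, 2) + rnorm(20)
  base <- icc_oneway_single(x)$icc
  expect_equal(icc_oneway_single(x + 100)$icc, base, tolerance = 1e-9)
  expect_equal(icc_oneway_single(x * 3.7)$icc, base, tolerance = 1e-9)
})

test_that("ICC confidence interval achieves nominal coverage", {
  set.seed(31)
  true_icc <- 0.7
  between_sd <- sqrt(true_icc); error_sd <- sqrt(1 - true_icc)
  hits <- 0L
  n_rep <- 1000L
  for (i in seq_len(n_rep)) {
    tab <- simulate_observer_ratings(rep(0, 20), between_sd, error_sd, k = 2)
    ci <- icc_oneway_single(tab)
    if (ci$ci_low <= true_icc && true_icc <= ci$ci_high) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.93)
  expect_lte(hits / n_rep, 0.97)
})

test_that("MAD/SD agreement summaries", {
  expect_equal(mad_sd(1:4, 1:4), list(mad = 0, sd = 0))
  expect_equal(mad_sd(c(2, 3, 4, 5), c(1, 2, 3, 4)), list(mad = 1, sd = 0))
  ms <- mad_sd(c(1, 2), c(0.5, 0.5))
  expect_equal(ms$mad, 1)
  expect_equal(ms$sd, sd(c(0.5, 1.5)))
  expect_error(mad_sd(1:3, 1:4), "equal length")
})

test_that("Bland-Altman bias and limits of agreement", {
  ba0 <- bland_altman(1:5, 1:5)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  ba_c <- bland_altman(1:5 + 2, 1:5)
  expect_equal(ba_c$bias, 2)
  expect_equal(c(ba_c$loa_low, ba_c$loa_high), c(2, 2))
  ba <- bland_altman(c(-1, 0, 1), c(0, 0, 0))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96, tolerance = 1e-12)
  # limits symmetric about the bias, data returned for plotting
  expect_equal(ba$loa_high - ba$bias, ba$bias - ba$loa_low)
  expect_identical(nrow(ba$data), 3L)

  # ~95% of differences fall inside the limits on large normal samples
  set.seed(12)
  x <- rnorm(10000); y <- rnorm(10000)
  bb <- bland_altman(x, y)
  inside <- mean(bb$data$diff >= bb$loa_low & bb$data$diff <= bb$loa_high)
  expect_lt(abs(inside - 0.95), 0.01)
})

test_that("Cicchetti bands and the >0.60 reliability criterion", {
  expect_identical(cicchetti_category(0.61)$category, "good")
  expect_true(cicchetti_category(0.61)$reliable)
  expect_identical(cicchetti_category(0.82)$category, "excellent")
  expect_identical(cicchetti_category(0.71)$category, "good")
  expect_identical(cicchetti_category(0.39)$category, "poor")
  expect_identical(cicchetti_category(0.5)$category, "fair")
  expect_false(cicchetti_category(0.5)$reliable)
  expect_error(cicchetti_category(NaN), "finite")
})

test_that("Fisher-z sample size calculation", {
  expect_identical(sample_size_one_correlation(0.6, 0.05, 0.8), 20L)
  expect_lte(sample_size_one_correlation(0.99, 0.05, 0.8), 6L)
  # closed-form oracle at power 0.9
  oracle <- ceiling(((qnorm(0.975) + qnorm(0.9)) / atanh(0.6))^2 + 3)
  expect_identical(sample_size_one_correlation(0.6, 0.05, 0.9),
                   as.integer(oracle))
  expect_error(sample_size_one_correlation(1.2), "rho_alt")
  expect_error(sample_size_one_correlation(0.6, alpha = 0), "alpha")
})

test_that("simulated ratings recover the design ICC", {
  tab <- simulate_observer_ratings(rnorm(10), between_sd = 1, error_sd = 0,
                                   k = 2, seed = 42)
  expect_equal(icc_oneway_single(tab)$icc, 1, tolerance = 1e-9)
  expect_equal(attr(tab, "true_icc"), 1)

  t1 <- simulate_observer_ratings(1:5, 2, 1, seed = 7)
  t2 <- simulate_observer_ratings(1:5, 2, 1, seed = 7)
  expect_identical(t1, t2)

  # mean estimate over replicates is within Monte-Carlo error of 0.8
  set.seed(99)
  est <- replicate(500, icc_oneway_single(
    simulate_observer_ratings(rep(0, 20), between_sd = 2, error_sd = 1))$icc)
  mc_err <- 3 * sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.8), max(mc_err, 0.02))
})

test_that("reliability_study assembles the per-cell agreement table", {
  rep1 <- data.frame(subject = rep(sprintf("s%02d", 1:8), each = 2),
                     structure = "condyle", region = "whole",
                     metric = rep(c("volumetric_change_pct", "mean_abs_distance_mm"), 8),
                     value = rnorm(16), stringsAsFactors = FALSE)
  rel <- reliability_study(rep1, rep1)
  expect_true(all(rel$icc == 1))
  expect_true(all(rel$mad == 0))
  expect_true(all(rel$category == "excellent"))

  rep2 <- rep1
  rep2$subject[1] <- "s99"
  expect_error(reliability_study(rep1, rep2), "unmatched")
})
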