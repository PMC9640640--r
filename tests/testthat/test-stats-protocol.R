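test_that("paired t-test matches the textbook formula and handles edge cases", {
  x <- c(1.0, 2.0, 3.0, 4.0); y <- c(1.1, 2.3, 2.8, 4.4)
  # frozen from direct evaluation of t = mean(d)/(sd(d)/sqrt(n)) and the
  # t CDF
  res <- paired_t(x, y)
  expect_equal(res$statistic, -1.13389341903, tolerance = 1e-9)
  expect_equal(res$p_value, 0.339254050856, tolerance = 1e-9)
  expect_equal(res$df, 3)
  # identical samples: zero statistic, p = 1
  z <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  # constant non-zero difference: undefined, must raise
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "constant")
  expect_error(paired_t(1, 2), "at least 2")
  expect_error(paired_t(1:3, 1:4), "paired")
  # two-sided tests are invariant to a sign flip of all differences
  expect_equal(paired_t(y, x)$p_value, res$p_value, tolerance = 1e-12)
})

test_that("one-sample t-test mirrors the paired construction", {
  d <- c(1.0, 2.0, 3.0, 4.0) - c(1.1, 2.3, 2.8, 4.4)
  res <- one_sample_t(d, 0)
  expect_equal(res$statistic, -1.13389341903, tolerance = 1e-9)
  expect_equal(res$p_value, 0.339254050856, tolerance = 1e-9)
  z <- one_sample_t(rep(0.5, 4), 0.5)
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  expect_error(one_sample_t(rep(1, 4), 0), "zero variance")
  expect_error(one_sample_t(3), "at least 2")
})

test_that("Friedman test matches the rank-formula oracle with Bonferroni cap", {
  m <- rbind(c(1, 2, 3), c(1, 2, 3), c(2, 1, 3), c(1, 3, 2))
  res <- friedman_bonferroni(m)
  # frozen by brute-force within-row ranking: rank sums 5, 8, 11 give
  # 12/(4*3*4)*(25+64+121) - 3*4*4 = 4.5
  expect_equal(res$overall$statistic, 4.5, tolerance = 1e-12)
  expect_equal(res$overall$p_value, 0.105399224562, tolerance = 1e-9)
  expect_equal(res$overall$df, 2)
  # adjusted p-values multiply by the 3 pairs and cap at 1
  expect_true(all(res$pairwise$p_adj <= 1))
  expect_equal(res$pairwise$p_adj,
               pmin(1, res$pairwise$p_raw * 3))
  # cap rule: a raw pairwise p of ~0.48 multiplied by 3 pairs is capped at 1
  m_cap <- rbind(c(1, 2, 3), c(2, 1, 3), c(1, 2, 3), c(2, 3, 1))
  rc <- friedman_bonferroni(m_cap)
  expect_equal(rc$pairwise$p_raw[1], 2 * pnorm(-2 / sqrt(8)),
               tolerance = 1e-12)
  expect_lt(rc$pairwise$p_raw[1], 1)
  expect_equal(rc$pairwise$p_adj[1], 1)
  # identical columns: zero statistic, all p = 1
  tie <- matrix(rep(c(1, 2, 4, 7), 3), ncol = 3)
  rt <- friedman_bonferroni(tie)
  expect_equal(rt$overall$statistic, 0)
  expect_equal(rt$overall$p_value, 1)
  expect_true(all(rt$pairwise$p_adj == 1))
  expect_error(friedman_bonferroni(matrix(c(1, NA, 2, 3), 2)), "missing")
  # invariant under a monotone transformation applied to whole rows
  res2 <- friedman_bonferroni(exp(m))
  expect_equal(res2$overall$statistic, res$overall$statistic)
})

test_that("KS normality screen matches the ECDF oracle and simulations", {
  xs <- c(-1.2, -0.4, 0.1, 0.7, 1.9)
  # frozen from brute-force max |ECDF - CDF| at the jump points
  expect_equal(ks_normality(xs)$statistic, 0.140873809111, tolerance = 1e-9)
  # draws from the reference normal keep p above 0.05 in >= 95% of seeds
  ps <- vapply(1:100, function(s) {
    set.seed(s)
    ks_normality(rnorm(100))$p_value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.95)
  # a uniform sample is flagged by the Lilliefors-corrected variant; the
  # nominal method is conservative because the reference parameters are
  # estimated from the sample, so its p is larger
  set.seed(1)
  u <- runif(200)
  expect_lt(ks_normality(u, lilliefors = TRUE)$p_value, 0.05)
  expect_gt(ks_normality(u)$p_value,
            ks_normality(u, lilliefors = TRUE)$p_value)
  expect_error(ks_normality(rnorm(4)), "at least 5")
})

test_that("Bland-Altman recovers bias and limits of agreement", {
  x <- c(23.1, 23.9, 25.2, 21.8)
  z <- bland_altman(x, x)
  expect_equal(c(z$bias, z$loa_low, z$loa_high), c(0, 0, 0))
  z2 <- bland_altman(x + 0.11, x)
  expect_equal(z2$bias, 0.11, tolerance = 1e-12)
  expect_equal(z2$sd_diff, 0)
  expect_equal(z2$loa_low, z2$loa_high)
  # LoA structure: bias +/- 1.96 sd of differences
  set.seed(8)
  a <- rnorm(50); b <- a + rnorm(50, 0.2, 0.3)
  z3 <- bland_altman(a, b)
  expect_equal(z3$loa_low, z3$bias - 1.96 * z3$sd_diff)
  expect_equal(z3$loa_high, z3$bias + 1.96 * z3$sd_diff)
  # default cohort pseudophakic-vs-phakic agreement recovers the
  # generator's -0.11 mm offset and 0.07 mm paired noise (3 SE slack)
  op <- operated(default_cohort(seed = 1))
  ba <- bland_altman(op$al_post_pseudophakic, op$al_pre_phakic)
  se <- 0.07 / sqrt(nrow(op))
  expect_lt(abs(ba$bias - (-0.11)), 3 * se)
  expect_lt(abs(ba$loa_low - (-0.11 - 1.96 * 0.07)), 0.05)
  expect_lt(abs(ba$loa_high - (-0.11 + 1.96 * 0.07)), 0.05)
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("paired sample size follows the noncentral-t iteration", {
  # the clinical design spec: 0.02 D difference, 0.08 D within-subject SD
  expect_identical(paired_t_sample_size(0.02, 0.08), 128L)
  # must exceed the normal-approximation lower bound
  zbound <- ceiling(((qnorm(0.975) + qnorm(0.8)) * 0.08 / 0.02)^2)
  expect_equal(zbound, 126)
  expect_gte(paired_t_sample_size(0.02, 0.08), zbound)
  # doubling delta reduces n roughly fourfold
  n2 <- paired_t_sample_size(0.04, 0.08)
  expect_identical(n2, 34L)
  expect_true(n2 >= 30 && n2 <= 36)
  # monotone: non-increasing in delta, non-decreasing in sigma and power
  expect_lte(paired_t_sample_size(0.03, 0.08), paired_t_sample_size(0.02, 0.08))
  expect_gte(paired_t_sample_size(0.02, 0.10), paired_t_sample_size(0.02, 0.08))
  expect_gte(paired_t_sample_size(0.02, 0.08, power = 0.9),
             paired_t_sample_size(0.02, 0.08, power = 0.8))
  expect_error(paired_t_sample_size(-1, 0.08), "positive")
  expect_error(paired_t_sample_size(0.02, 0.08, alpha = 1.5), "in \\(0, 1\\)")
})
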