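test_that("Bland-Altman matches a direct recomputation and handles degenerate input", {
  set.seed(41)
  a <- rlnorm(20, 7.9, 0.4); b <- rlnorm(20, 7.9, 0.35)
  ba <- bland_altman(a, b)
  o <- oracle_bland_altman(a, b)
  expect_equal(ba$bias, o$bias)
  expect_equal(ba$sd_diff, o$sd_diff)
  expect_equal(ba$loa_lower, o$loa_lower)
  expect_equal(ba$loa_upper, o$loa_upper)
  expect_equal(ba$pct_within_loa, o$pct_within)
  expect_true(ba$loa_lower <= ba$bias && ba$bias <= ba$loa_upper)
  # slope against an independent least-squares fit
  d <- a - b; m <- (a + b) / 2
  sxx <- sum((m - mean(m))^2)
  slope <- sum((m - mean(m)) * (d - mean(d))) / sxx
  expect_equal(ba$prop_bias_slope, slope)
  # identical vectors: zero bias/SD, limits collapse, slope flagged
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$bias, 0); expect_equal(ba0$sd_diff, 0)
  expect_true(ba0$zero_variance)
  expect_true(is.na(ba0$prop_bias_slope))
  expect_equal(ba0$pct_within_loa, 100)
  # constant shift: bias = shift, sd 0
  ba10 <- bland_altman(a + 10, a)
  expect_equal(ba10$bias, 10); expect_equal(ba10$sd_diff, 0)
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman quantities are invariant under a common shift", {
  set.seed(42)
  a <- rlnorm(15, 7.9, 0.3); b <- rlnorm(15, 7.9, 0.3)
  ba <- bland_altman(a, b)
  sh <- bland_altman(a + 500, b + 500)
  expect_equal(sh$bias, ba$bias)
  expect_equal(sh$sd_diff, ba$sd_diff)
  expect_equal(sh$loa_lower, ba$loa_lower)
  expect_equal(sh$prop_bias_slope, ba$prop_bias_slope)
  expect_equal(sh$prop_bias_p, ba$prop_bias_p)
})

test_that("paired t equals the brute-force mean/SE ratio on each transform", {
  set.seed(43)
  a <- rlnorm(10, 7.9, 0.4); b <- rlnorm(10, 7.9, 0.4)
  for (tr in c("none", "sqrt", "log")) {
    pt <- paired_t(a, b, transform = tr)
    ta <- switch(tr, none = a, sqrt = sqrt(a), log = log(a))
    tb <- switch(tr, none = b, sqrt = sqrt(b), log = log(b))
    o <- oracle_paired_t(ta, tb)
    expect_equal(pt$t_stat, o$t)
    expect_identical(pt$df, 9L)
    # effect summaries stay on the original scale
    expect_equal(pt$mean_diff, mean(a - b))
    expect_equal(pt$cohen_d, mean(a - b) / sd(a - b))
    expect_equal(pt$pct_mean_diff, (mean(a) - mean(b)) / mean(b) * 100)
  }
  # identical vectors: zero difference, flagged t
  pt0 <- paired_t(a, a)
  expect_equal(pt0$mean_diff, 0)
  expect_equal(pt0$cohen_d, 0)
  expect_true(pt0$zero_variance)
  expect_error(paired_t(c(-1, 2), c(1, 2), transform = "sqrt"), "non-negative")
  expect_error(paired_t(c(0, 2), c(1, 2), transform = "log"), "positive")
})

test_that("percent mean difference follows its defining formula", {
  expect_equal(pct_mean_difference(2735, 2742), (2735 - 2742) / 2742 * 100)
  expect_equal(pct_mean_difference(2000, 2000), 0)
  expect_equal(round(pct_mean_difference(3185, 2725), 2), 16.88)
  expect_error(pct_mean_difference(1, 0), "nonzero")
})

test_that("de-attenuation applies the replicate correction and never shrinks |r|", {
  expect_equal(as.numeric(deattenuate(0.3, 0, 3)), 0.3)      # identity at lambda 0
  expect_equal(round(as.numeric(deattenuate(0.202, 0.49, 3)), 4), 0.2179)
  set.seed(44)
  for (i in 1:20) {
    r <- runif(1, -1, 1); lam <- runif(1, 0, 3); k <- sample(1:5, 1)
    rc <- deattenuate(r, lam, k)
    expect_gte(abs(as.numeric(rc)) + 1e-12, abs(r))
    expect_equal(as.numeric(rc),
                 max(-1, min(1, r * sqrt(1 + lam / k))))
  }
  rc <- deattenuate(0.9, 3, 1)
  expect_equal(as.numeric(rc), 1)
  expect_true(attr(rc, "clipped"))
  expect_error(deattenuate(1.2, 0.5, 3), "r_observed")
})

test_that("kappa matches the brute-force chance-corrected agreement", {
  set.seed(45)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 20) + 1, 2, 2)
    k <- cohens_kappa(tab)
    o <- oracle_kappa(tab)
    expect_equal(k$kappa, o$kappa)
    expect_equal(k$p_observed, o$po)
    expect_equal(k$p_expected, o$pe)
    # symmetric under transposition
    expect_equal(cohens_kappa(t(tab))$kappa, k$kappa)
  }
  # diagonal-only table with both classes represented: kappa 1
  expect_equal(cohens_kappa(matrix(c(30, 0, 0, 70), 2))$kappa, 1)
  expect_identical(cohens_kappa(matrix(c(30, 0, 0, 70), 2))$band_label, "perfect")
  # off-diagonal mass means kappa < 1
  expect_lt(cohens_kappa(matrix(c(30, 1, 0, 69), 2))$kappa, 1)
  # degenerate all-one-cell table: expected agreement 1, kappa undefined
  und <- cohens_kappa(matrix(c(10, 0, 0, 0), 2))
  expect_true(und$undefined)
  expect_true(is.na(und$kappa))
})

test_that("kappa accepts classification vectors and bands follow Landis-Koch", {
  a <- factor(c("x", "x", "y", "y", "y"))
  b <- factor(c("x", "y", "y", "y", "x"))
  k <- cohens_kappa(a, b)
  tab <- table(a, b)
  expect_equal(k$kappa, oracle_kappa(unclass(as.matrix(tab)))$kappa)
  expect_identical(saltscreener:::kappa_band(0.15), "poor")
  expect_identical(saltscreener:::kappa_band(0.236), "fair")
  expect_identical(saltscreener:::kappa_band(0.488), "moderate")
  expect_identical(saltscreener:::kappa_band(0.75), "substantial")
  expect_identical(saltscreener:::kappa_band(0.9), "almost perfect")
  expect_identical(saltscreener:::kappa_band(1), "perfect")
})

test_that("cross-classification percentages match brute-force counting", {
  expect_equal(cross_classify(1:4, 1:4)$pct_same, 100)
  expect_equal(cross_classify(rep(1, 5), rep(4, 5))$pct_gross, 100)
  expect_equal(cross_classify(rep(1, 5), rep(4, 5))$pct_same, 0)
  set.seed(46)
  qa <- sample(1:4, 100, replace = TRUE)
  qb <- sample(1:4, 100, replace = TRUE)
  cc <- cross_classify(qa, qb)
  same <- 0; adj <- 0; gross <- 0
  for (i in 1:100) {
    d <- abs(qa[i] - qb[i])
    if (d == 0) same <- same + 1
    if (d <= 1) adj <- adj + 1
    if (d == 3) gross <- gross + 1
  }
  expect_equal(cc$pct_same, same)
  expect_equal(cc$pct_same_or_adjacent, adj)
  expect_equal(cc$pct_gross, gross)
  expect_equal(sum(cc$joint_table), 100)
  expect_lte(cc$pct_same, cc$pct_same_or_adjacent)
  expect_error(cross_classify(1:4, 1:5), "equal length")
})

test_that("Cronbach's alpha matches the variance arithmetic", {
  set.seed(47)
  m <- matrix(rlnorm(15, 4, 0.5), 5, 3)
  expect_equal(cronbach_alpha(m), oracle_alpha(m))
  # identical copies of one variable: alpha = 1
  x <- rnorm(30)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1)
  # independent items: alpha near 0 at large n
  set.seed(48)
  big <- matrix(rnorm(4000 * 4), 4000, 4)
  expect_lt(abs(cronbach_alpha(big)), 0.08)
  expect_error(cronbach_alpha(matrix(1, 5, 3)), "zero total-score variance")
})

test_that("skewness and its SE match the moment formulas", {
  set.seed(49)
  x <- rlnorm(50, 7.9, 0.4)
  sk <- skewness_with_se(x)
  expect_equal(sk$skewness, oracle_skewness(x))
  n <- 50
  expect_equal(sk$se, sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3))))
  # symmetric data: zero skewness
  expect_equal(skewness_with_se(c(-2, -1, 1, 2))$skewness, 0)
  # constant data flagged
  expect_true(skewness_with_se(rep(3, 10))$zero_variance)
})

test_that("boxplot fences flag outliers and extreme values", {
  x <- c(1:20, 1000)
  bo <- boxplot_outliers(x)
  expect_identical(bo$outliers, 21L)
  expect_identical(bo$extremes, 21L)
  expect_identical(boxplot_outliers(rep(5, 6))$outliers, integer(0))
  set.seed(50)
  y <- rlnorm(40, 7.9, 0.5)
  bo <- boxplot_outliers(y)
  q <- quantile(y, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  expect_identical(bo$outliers,
                   which(y < q[1] - 1.5 * iqr | y > q[2] + 1.5 * iqr))
  expect_identical(bo$extremes,
                   which(y < q[1] - 3 * iqr | y > q[2] + 3 * iqr))
  expect_true(all(bo$extremes %in% bo$outliers))
})

test_that("limits-of-agreement sample size is the minimal n meeting the CV target", {
  n <- ba_sample_size(75, 457, 0.10)
  expect_true(n >= 90 && n <= 95) # low 90s for these planning values
  cv <- function(n, d = 75, s = 457, z = 1.96)
    s * sqrt(1 / n + z^2 / (2 * (n - 1))) / abs(d - z * s)
  expect_lte(cv(n), 0.10)
  expect_gt(cv(n - 1), 0.10)
  # generous target hits the floor of 3
  expect_identical(ba_sample_size(75, 457, 0.9), 3L)
  expect_error(ba_sample_size(75, 0, 0.1), "sd_diff")
})

test_that("Spearman correlation uses average ranks for ties", {
  x <- 1:10
  expect_equal(spearman_corr(x, x * 2 + 3)$rho, 1)
  expect_equal(spearman_corr(x, rev(x))$rho, -1)
  xt <- c(1, 2, 2, 3, 4, 4, 4, 5)
  yt <- c(2, 1, 3, 3, 5, 4, 6, 7)
  expect_equal(spearman_corr(xt, yt)$rho, oracle_spearman(xt, yt))
  expect_true(spearman_corr(rep(1, 5), 1:5)$undefined)
})
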