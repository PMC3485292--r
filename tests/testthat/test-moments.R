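# Central-moments analysis, Fisher indices, and the significance battery.

test_that("central_moments matches direct-formula oracles and handles edge cases", {
  expect_equal(central_moments(c(-1, 0, 1, -1, 0, 1))$skewness, 0)
  m <- central_moments(c(1, 2, 3, 4, 10))
  o <- oracle_moments(c(1, 2, 3, 4, 10))
  expect_equal(m$mean, o$mean, tolerance = 1e-12)
  expect_equal(m$variance, o$variance, tolerance = 1e-12)
  expect_equal(m$skewness, o$skewness, tolerance = 1e-12)
  expect_equal(m$excess_kurtosis, o$excess_kurtosis, tolerance = 1e-12)
  cst <- central_moments(rep(4, 10))
  expect_true(cst$degenerate)
  expect_identical(cst$variance, 0)
  expect_true(is.na(cst$skewness) && is.na(cst$excess_kurtosis))
  expect_false(is.nan(cst$skewness))
})

test_that("Fisher indices reproduce the printed large-sample arithmetic", {
  n <- 9841500
  expect_equal(signif(fisher_skewness_index(-1.640, n), 2), -2100)
  expect_equal(signif(fisher_skewness_index(0.827, n), 3), 1060)
  expect_equal(signif(fisher_kurtosis_index(17.590, n), 2), 11000)
  expect_equal(signif(fisher_kurtosis_index(3.912, n), 2), 2500)
  expect_identical(fisher_skewness_index(0, 100), 0)
  expect_identical(fisher_kurtosis_index(0, 100), 0)
})

test_that("Fisher indices scale as sqrt(n)", {
  for (g in c(-0.4, 0.1, 2)) {
    for (n in c(25, 400)) {
      expect_equal(fisher_skewness_index(g, 4 * n),
                   2 * fisher_skewness_index(g, n), tolerance = 1e-14)
      expect_equal(fisher_kurtosis_index(g, 4 * n),
                   2 * fisher_kurtosis_index(g, n), tolerance = 1e-14)
    }
  }
})

test_that("exact small-sample standard errors are available and larger-sample consistent", {
  # exact formulas converge to sqrt(6/n), sqrt(24/n)
  expect_equal(se_skewness(1e6, exact = TRUE), sqrt(6 / 1e6), tolerance = 1e-5)
  expect_equal(se_kurtosis(1e6, exact = TRUE), sqrt(24 / 1e6), tolerance = 1e-4)
  # at n = 10 they differ materially from the large-sample form
  expect_gt(abs(se_skewness(10, exact = TRUE) - sqrt(0.6)) / sqrt(0.6), 0.05)
})

test_that("the simulated normal reference is seed-stable with correct moments", {
  x <- simulate_normal_reference(1e6, seed = 12)
  expect_identical(x, simulate_normal_reference(1e6, seed = 12))
  expect_lt(abs(mean(x)), 4 / sqrt(1e6))
  expect_lt(abs(sample_skewness(x)), 4 * sqrt(6 / 1e6))
  # chi-square bound on the sample variance at 4 SE
  expect_true(stats::var(x) > 0.994 && stats::var(x) < 1.006)
})

test_that("mean tests agree with a brute-force Wilcoxon enumeration on tiny samples", {
  x <- c(0.3, -1.2, 0.8, 1.9, -0.4, 0.6)
  y <- c(1.4, 2.2, -0.1, 1.1, 2.8, 0.9)
  mt <- mean_tests(x, y)
  expect_equal(mt$wilcoxon_p, oracle_wilcoxon_exact(x, y), tolerance = 1e-12)
  expect_equal(mt$t_p, stats::t.test(x, y)$p.value, tolerance = 1e-12)
  z <- stats::rnorm(50)
  same <- mean_tests(z, z)
  expect_gt(same$t_p, 0.99)
  expect_gt(same$wilcoxon_p, 0.99)
  shifted <- mean_tests(z, z + 10)
  expect_lt(shifted$t_p, 1e-10)
  expect_lt(shifted$wilcoxon_p, 1e-10)
})

test_that("variance test p-values are uniform under the null and its CI matches chi-square quantiles", {
  set.seed(99)
  p <- replicate(200, variance_test(stats::rnorm(100))$f_p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  x <- c(2.1, 0.3, -1.2, 0.8, 1.9, -0.4, 0.6, 1.4, -2, 0.5)
  vt <- variance_test(x)
  s2 <- sum((x - mean(x))^2) / 9
  expect_equal(vt$ci,
               c(9 * s2 / stats::qchisq(0.975, 9), 9 * s2 / stats::qchisq(0.025, 9)),
               tolerance = 1e-10)
  expect_error(variance_test(rep(1, 5)), "degenerate")
})

test_that("one-sample KS statistic, p and critical value follow the contracts", {
  # single observation at the normal median: D = 0.5
  expect_equal(ks_one_sample(0)$D, 0.5)
  # critical value at the pooled-cancer feature count prints as 0.0004
  expect_equal(signif(ks_critical_value(9841500, 0.05), 1), 4e-4)
  expect_equal(ks_critical_value(100, 0.05), 1.3581 / 10, tolerance = 1e-4)
  # strictly decreasing in n
  ns <- c(10, 100, 1000, 1e5)
  expect_true(all(diff(ks_critical_value(ns)) < 0))
  # asymptotic p agrees with the stats::ks.test oracle on a large sample
  set.seed(5)
  x <- stats::rnorm(5000)
  ours <- ks_one_sample(x)
  ref <- stats::ks.test(x, "pnorm", exact = FALSE)
  expect_equal(ours$D, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-6)
})

test_that("samples from the reference rarely reject the one-sample KS test", {
  set.seed(21)
  p <- replicate(200, ks_one_sample(stats::rnorm(1e4))$p)
  expect_gte(mean(p > 0.001), 0.99)
})

test_that("two-sample KS matches the direct sup-difference oracle", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(0, 1), c(2, 3))$D, 1)
  set.seed(8)
  for (i in 1:10) {
    a <- stats::rnorm(30)
    b <- stats::rnorm(40, 0.5)
    expect_equal(ks_two_sample(a, b)$D, oracle_ks2(a, b), tolerance = 1e-12)
  }
  a <- stats::rnorm(500); b <- stats::rnorm(600)
  expect_equal(ks_two_sample(a, b)$D,
               unname(stats::ks.test(a, b, exact = FALSE)$statistic),
               tolerance = 1e-12)
})

test_that("per-gene moments match direct formulas and flag constant genes", {
  em <- gen_matrix(dist_spec("normal", c(0.5, 2), 50), 30, seed = 44)
  m <- em$values
  m["g00007", ] <- 3 # constant gene
  pg <- per_gene_moments(m, kurtosis = "excess")
  set.seed(3)
  for (i in sample(setdiff(1:50, 7), 10)) {
    o <- oracle_moments(m[i, ])
    expect_equal(unname(pg$sd[i]), sqrt(o$variance), tolerance = 1e-12)
    expect_equal(unname(pg$skewness[i]), o$skewness, tolerance = 1e-12)
    expect_equal(unname(pg$kurtosis[i]), o$excess_kurtosis, tolerance = 1e-12)
  }
  expect_equal(pg$n_constant, 1L)
  expect_identical(pg$constant_genes, "g00007")
  expect_false(any(is.na(pg$aggregates)))
})

test_that("shape moments are location-free and behave under negation", {
  set.seed(10)
  x <- stats::rexp(200)
  expect_equal(sample_skewness(x + 5), sample_skewness(x), tolerance = 1e-9)
  expect_equal(sample_skewness(-x), -sample_skewness(x), tolerance = 1e-12)
  expect_equal(sample_excess_kurtosis(-x), sample_excess_kurtosis(x),
               tolerance = 1e-12)
  expect_equal(stats::sd(x + 3), stats::sd(x), tolerance = 1e-12)
})

test_that("a large simulated normal fails to reject skewness/kurtosis at alpha = 0.01", {
  ok <- 0L
  for (s in 1:20) {
    x <- simulate_normal_reference(1e5, seed = 300 + s)
    m <- central_moments(x)
    z <- stats::qnorm(1 - 0.01 / 2)
    if (abs(m$fisher_skew_index) <= z && abs(m$fisher_kurt_index) <= z)
      ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("normality_report flags a skewed dataset but not a normal one", {
  ref <- simulate_normal_reference(2e5, seed = 1)
  x <- as.numeric(gen_matrix(skewed_noise_spec(500), 100, seed = 2)$values)
  rep_skew <- normality_report(x, reference = ref)
  expect_true(rep_skew$verdict$skew_nonnormal)
  expect_true(rep_skew$verdict$kurt_nonnormal)
  expect_true(rep_skew$verdict$ks_nonnormal)
  xn <- simulate_normal_reference(5e4, seed = 3)
  rep_norm <- normality_report(xn, reference = ref)
  expect_false(rep_norm$verdict$skew_nonnormal)
  expect_false(rep_norm$verdict$ks_nonnormal)
  expect_true(all(vapply(list(rep_norm$t_test_p, rep_norm$wilcoxon_p,
                              rep_norm$f_test_p, rep_norm$ks1_p),
                         function(p) p >= 0 && p <= 1, logical(1))))
})
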