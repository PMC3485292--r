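# The four differential-expression callers.

make_labeled <- function(n_genes, n1 = 8, n2 = 6, seed = 1, n_de = 0,
                         effect = 0, sdv = 1) {
  gen_two_class(two_class_design(n_genes, n1, n2, n_de = n_de,
                                 effect_size = effect,
                                 noise = dist_spec("normal", c(0, sdv)),
                                 seed = seed))
}

test_that("per-gene t statistics and p-values match the stats::t.test oracle", {
  em <- make_labeled(50, seed = 71)
  res <- ttest_bonferroni(em)
  i1 <- which(em$labels == "Class1"); i2 <- which(em$labels == "Class2")
  set.seed(1)
  for (i in sample(50, 10)) {
    tt <- stats::t.test(em$values[i, i2], em$values[i, i1], var.equal = TRUE)
    expect_equal(unname(res$statistic[i]), unname(tt$statistic), tolerance = 1e-10)
    expect_equal(unname(res$p_raw[i]), tt$p.value, tolerance = 1e-10)
  }
  # Bonferroni with a single gene: adjusted equals raw
  one <- ttest_bonferroni(em$values[1, , drop = FALSE], em$labels)
  expect_equal(unname(one$p_adjusted), unname(one$p_raw))
})

test_that("the Bonferroni t controls familywise error on null designs", {
  false_calls <- vapply(1:100, function(s) {
    em <- make_labeled(5000, n1 = 12, n2 = 8, seed = 1000 + s)
    length(ttest_bonferroni(em, alpha = 0.01)$called)
  }, numeric(1))
  expect_gte(mean(false_calls == 0), 0.99)
})

test_that("the Bonferroni t recovers strongly planted genes", {
  em <- make_labeled(2000, n1 = 15, n2 = 8, seed = 72, n_de = 50,
                     effect = 3, sdv = 0.5)
  called <- ttest_bonferroni(em, alpha = 0.01)$called
  expect_gte(length(intersect(called, sprintf("g%05d", 1:50))), 45)
})

test_that("zero-variance genes are handled per the documented rule", {
  em <- make_labeled(20, seed = 73)
  em$values[1, ] <- rep(c(0, 1), times = c(8, 6)) # zero within-class variance, shifted
  em$values[2, ] <- 5                              # fully constant
  res <- ttest_bonferroni(em)
  expect_true(is.infinite(res$statistic[1]))
  expect_identical(unname(res$p_raw[1]), 0)
  expect_true("g00001" %in% res$called)
  expect_true(is.na(res$statistic[2]))
  expect_false("g00002" %in% res$called)
  expect_match(res$notes, "zero-variance")
})

test_that("SAM with s0 = 0 reduces to the plain mean-difference ratio", {
  em <- make_labeled(100, seed = 74)
  i1 <- which(em$labels == "Class1"); i2 <- which(em$labels == "Class2")
  d <- exprdist:::sam_d(em$values, i1, i2, s0 = 0)
  st <- exprdist:::pooled_gene_stats(em$values, i1, i2)
  expect_equal(d, (st$mean2 - st$mean1) / st$se, tolerance = 1e-14)
})

test_that("SAM at FDR = 0 is near-empty under the null", {
  # median FDR estimator (the classic recipe): the far-tail median is
  # coarse, so a couple of extreme null genes can slip through a zero
  # estimate -- but never more than a handful (here <= 1% of genes), and
  # most replicates call nothing
  n_med <- vapply(1:50, function(s) {
    em <- make_labeled(500, n1 = 8, n2 = 6, seed = 2000 + s)
    length(sam_two_class(em, target_fdr = 0, n_perm = 100, seed = s)$called)
  }, numeric(1))
  expect_lte(max(n_med), 5)
  expect_gte(mean(n_med == 0), 0.6)
  # the mean estimator is strict in the far tail: at most one gene in
  # >= 95% of replicates
  n_mean <- vapply(1:50, function(s) {
    em <- make_labeled(500, n1 = 8, n2 = 6, seed = 2000 + s)
    length(sam_two_class(em, target_fdr = 0, n_perm = 100, seed = s,
                         fdr_estimator = "mean")$called)
  }, numeric(1))
  expect_gte(mean(n_mean <= 1), 0.95)
})

test_that("SAM recovers planted genes at a permissive FDR and is seed-stable", {
  em <- make_labeled(1000, n1 = 15, n2 = 8, seed = 75, n_de = 50,
                     effect = 3, sdv = 0.5)
  res <- sam_two_class(em, target_fdr = 0.05, n_perm = 200, seed = 7)
  expect_gte(length(intersect(res$called, sprintf("g%05d", 1:50))), 40)
  res2 <- sam_two_class(em, target_fdr = 0.05, n_perm = 200, seed = 7)
  expect_identical(res$called, res2$called)
  expect_identical(res$params$delta, res2$params$delta)
  # doubling the permutation count moves the estimated FDR only slightly
  res4 <- sam_two_class(em, target_fdr = 0.05, n_perm = 400, seed = 7)
  expect_lt(abs(res$params$estimated_fdr - res4$params$estimated_fdr), 0.01)
})

test_that("SAM enumerates the permutation space in full when it is small", {
  em <- make_labeled(60, n1 = 4, n2 = 3, seed = 76)
  res <- sam_two_class(em, n_perm = 100, seed = 1)
  expect_true(res$params$enumerated)
  expect_identical(res$params$n_perm, as.integer(choose(7, 4)))
})

test_that("Kruskal-Wallis matches oracles and is monotone-invariant", {
  em <- make_labeled(40, n1 = 4, n2 = 4, seed = 77)
  res <- kruskal_wallis_bh(em)
  # independent direct-formula oracle and the base kruskal.test oracle
  for (i in c(1, 13, 40)) {
    v <- em$values[i, ]
    expect_equal(unname(res$statistic[i]), oracle_kw_h(v, em$labels),
                 tolerance = 1e-12)
    kt <- stats::kruskal.test(v, factor(em$labels))
    expect_equal(unname(res$statistic[i]), unname(kt$statistic),
                 tolerance = 1e-12)
    expect_equal(unname(res$p_raw[i]), kt$p.value, tolerance = 1e-12)
  }
  # ties: duplicate some values and recheck against kruskal.test
  em$values[3, ] <- round(em$values[3, ])
  res_t <- kruskal_wallis_bh(em)
  kt <- stats::kruskal.test(em$values[3, ], factor(em$labels))
  expect_equal(unname(res_t$statistic[3]), unname(kt$statistic),
               tolerance = 1e-12)
  # an all-tied gene carries p = 1
  em$values[4, ] <- 2
  expect_equal(unname(kruskal_wallis_bh(em)$p_raw[4]), 1)
  # calls are invariant under any strictly monotone transform
  de <- make_labeled(300, n1 = 10, n2 = 8, seed = 78, n_de = 30, effect = 2)
  r1 <- kruskal_wallis_bh(de)
  shifted <- de$values - min(de$values) + 0.5
  r2 <- kruskal_wallis_bh(box_cox_apply(shifted, 0.3), de$labels)
  expect_identical(r1$called, r2$called)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
})

test_that("BH with a single gene leaves the p-value unchanged", {
  em <- make_labeled(30, seed = 79, n_de = 3, effect = 4)
  one <- kruskal_wallis_bh(em$values[1, , drop = FALSE], em$labels)
  expect_equal(unname(one$p_adjusted), unname(one$p_raw))
})

test_that("moderated t recovers its limiting forms exactly", {
  em <- make_labeled(200, seed = 80, n_de = 20, effect = 1.5)
  ord <- ttest_bonferroni(em)
  # d0 -> 0: ordinary t-statistics
  m0 <- moderated_t(em, d0 = 0)
  expect_equal(m0$statistic, ord$statistic, tolerance = 1e-12)
  expect_equal(m0$p_raw, ord$p_raw, tolerance = 1e-12)
  # d0 -> Inf: every denominator uses the prior variance
  minf <- moderated_t(em, d0 = Inf)
  i1 <- which(em$labels == "Class1"); i2 <- which(em$labels == "Class2")
  st <- exprdist:::pooled_gene_stats(em$values, i1, i2)
  manual <- (st$mean2 - st$mean1) /
    sqrt(minf$params$s0_sq * (1 / st$n1 + 1 / st$n2))
  expect_equal(unname(minf$statistic), unname(manual), tolerance = 1e-12)
})

test_that("moderated t hyperparameters agree with the limma oracle", {
  # heterogeneous gene variances so the prior df is finite
  set.seed(81)
  sds <- sqrt(1 / stats::rgamma(300, shape = 4, rate = 4))
  m <- matrix(stats::rnorm(300 * 14, sd = rep(sds, 14)), nrow = 300)
  rownames(m) <- sprintf("g%05d", 1:300)
  labels <- rep(c("A", "B"), c(8, 6))
  res <- moderated_t(m, labels)
  i1 <- which(labels == "A"); i2 <- which(labels == "B")
  st <- exprdist:::pooled_gene_stats(m, i1, i2)
  sq <- limma::squeezeVar(st$pooled_var, df = st$n1 + st$n2 - 2)
  expect_equal(res$params$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(res$params$s0_sq, sq$var.prior, tolerance = 1e-6)
  post <- (res$params$d0 * res$params$s0_sq +
             (st$n1 + st$n2 - 2) * st$pooled_var) / (res$params$d0 + st$n1 + st$n2 - 2)
  expect_equal(post, sq$var.post, tolerance = 1e-6)
})

test_that("moderated t p-values are approximately uniform under the null", {
  set.seed(82)
  sds <- sqrt(1 / stats::rgamma(2000, shape = 4, rate = 4))
  m <- matrix(stats::rnorm(2000 * 23, sd = rep(sds, 23)), nrow = 2000)
  rownames(m) <- sprintf("g%05d", 1:2000)
  labels <- rep(c("A", "B"), c(15, 8))
  p <- moderated_t(m, labels)$p_raw
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("callers are equivariant to gene order and global scaling", {
  em <- make_labeled(120, seed = 83, n_de = 15, effect = 2)
  set.seed(84)
  perm <- sample(120)
  mp <- em$values[perm, ]
  r1 <- ttest_bonferroni(em)
  r2 <- ttest_bonferroni(mp, em$labels)
  expect_setequal(r1$called, r2$called)
  expect_equal(r2$statistic, r1$statistic[perm], tolerance = 1e-12)
  # global scaling: t statistics unchanged, calls identical
  r3 <- ttest_bonferroni(em$values * 3.7, em$labels)
  expect_equal(r3$statistic, r1$statistic, tolerance = 1e-10)
  expect_identical(r3$called, r1$called)
  k1 <- kruskal_wallis_bh(em)
  k2 <- kruskal_wallis_bh(em$values * 3.7, em$labels)
  expect_identical(k1$called, k2$called)
  s1 <- sam_two_class(em, n_perm = 50, seed = 5, target_fdr = 0.1)
  s2 <- sam_two_class(em$values * 3.7, em$labels, n_perm = 50, seed = 5,
                      target_fdr = 0.1)
  expect_identical(s1$called, s2$called)
})
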