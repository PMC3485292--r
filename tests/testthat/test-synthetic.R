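# Synthetic-data generators: determinism, distributional correctness,
# two-class designs, reference profiles, annotation tables.

test_that("all generators are bit-identical for a fixed seed", {
  sp <- list(dist_spec("normal", c(0, 1), 50), skewed_noise_spec(30))
  expect_identical(gen_matrix(sp, 12, seed = 5), gen_matrix(sp, 12, seed = 5))
  d <- skewed_design(100, 10, 1.5, seed = 9)
  expect_identical(gen_two_class(d), gen_two_class(d))
  expect_identical(gen_reference_profiles(40, 3, seed = 3),
                   gen_reference_profiles(40, 3, seed = 3))
  a1 <- gen_annotation(100, 5, term_sizes = 10, seed = 4)
  a2 <- gen_annotation(100, 5, term_sizes = 10, seed = 4)
  expect_identical(a1, a2)
})

test_that("an all-normal matrix has Gaussian pooled moments", {
  em <- gen_matrix(dist_spec("normal", c(0, 1), 5000), 180, seed = 101)
  x <- as.numeric(em$values)
  n <- length(x)
  expect_equal(n, 5000 * 180)
  expect_lt(abs(sample_skewness(x)), 3 * sqrt(6 / n))
  expect_lt(abs(sample_excess_kurtosis(x)), 3 * sqrt(24 / n))
})

test_that("Johnson SU noise with negative gamma is right-skewed, per closed form", {
  par <- c(-1, 1.5, 0, 1)
  expect_gt(jsu_moments(par)$skew, 0) # closed-form oracle fixes the sign
  em <- gen_matrix(dist_spec("johnson_su", par, 2000), 100, seed = 7)
  x <- as.numeric(em$values)
  expect_gt(sample_skewness(x), 3 * sqrt(6 / length(x)))
})

test_that("pooled sample moments converge to the family closed forms", {
  n <- 1e6
  cases <- list(
    list(fam = "laplace", par = c(0.3, 0.9)),
    list(fam = "logistic", par = c(-0.2, 1.1)),
    list(fam = "hypsecant", par = c(0.5, 0.8)),
    list(fam = "johnson_su", par = c(-0.6, 1.6, 0, 1))
  )
  for (case in cases) {
    fam <- get_family(case$fam)
    truth <- fam$moments(case$par)
    if (is.null(truth)) truth <- jsu_moments(case$par)
    x <- as.numeric(gen_matrix(dist_spec(case$fam, case$par, 1000),
                               1000, seed = 31)$values)
    checks <- list(
      c(mean(x), truth$mean, block_se(x, mean)),
      c(stats::var(x), truth$var, block_se(x, stats::var)),
      c(sample_skewness(x), truth$skew, block_se(x, sample_skewness)),
      c(sample_excess_kurtosis(x), truth$exkurt,
        block_se(x, sample_excess_kurtosis))
    )
    for (ch in checks)
      expect_lt(abs(ch[1] - ch[2]), 4 * ch[3],
                label = sprintf("%s moment (%.4f vs %.4f)", case$fam,
                                ch[1], ch[2]))
  }
})

test_that("per-gene moments of an all-normal matrix sit at the Gaussian anchors", {
  em <- gen_matrix(dist_spec("normal", c(0, 1), 1000), 180, seed = 55)
  pg <- per_gene_moments(em, estimator = "bias_corrected", kurtosis = "plain")
  expect_lt(abs(pg$aggregates["sd", "mean"] - 1), 0.05)
  expect_lt(abs(pg$aggregates["skewness", "mean"]), 0.05)
  expect_lt(abs(pg$aggregates["kurtosis", "mean"] - 3), 0.05)
})

test_that("a null two-class design yields uniform t-test p-values", {
  d <- two_class_design(2000, 15, 8, n_de = 0, seed = 17)
  em <- gen_two_class(d)
  p <- ttest_bonferroni(em)$p_raw
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("a zero-effect design is identical to the null design", {
  base <- two_class_design(500, 10, 6, n_de = 0, seed = 3)
  zero_eff <- two_class_design(500, 10, 6, n_de = 50, effect_size = 0, seed = 3)
  expect_identical(gen_two_class(base), gen_two_class(zero_eff))
})

test_that("planted genes are recovered with high power under strong shifts", {
  d <- two_class_design(2000, 15, 8, n_de = 50, effect_size = 3,
                        noise = dist_spec("normal", c(0, 0.5)), seed = 23)
  em <- gen_two_class(d)
  called <- ttest_bonferroni(em, alpha = 0.01)$called
  planted <- rownames(em$values)[1:50]
  expect_gte(length(intersect(called, planted)), 45)
})

test_that("design invariants are enforced", {
  expect_error(two_class_design(10, 5, 5, n_de = 11), "design error")
  expect_error(two_class_design(10, 1, 5), ">= 2 samples")
})

test_that("reference profiles are positive, and identical on request", {
  m <- gen_reference_profiles(200, 3, seed = 8)
  expect_true(all(m > 0))
  expect_equal(dim(m), c(200L, 3L))
  mi <- gen_reference_profiles(50, 3, seed = 8, identical_profiles = TRUE)
  expect_identical(mi[, 1], mi[, 2])
  expect_identical(mi[, 1], mi[, 3])
})

test_that("annotation tables honor planted terms and reject duplicates", {
  genes <- sprintf("g%05d", 1:100)
  ann <- gen_annotation(100, 3, term_sizes = 10,
                        planted = list(DE_SET = genes[1:15]), seed = 6)
  expect_setequal(ann$terms$DE_SET, genes[1:15])
  expect_length(ann$terms, 4)
  expect_error(
    gen_annotation(100, 0, planted = list(A = genes[1:3], A = genes[4:6]),
                   seed = 1),
    "duplicate term names")
  empty <- gen_annotation(100, 0, seed = 2)
  expect_length(empty$terms, 0)
  res <- enrich(genes[1:5], empty)
  expect_identical(res$called_terms, character(0))
  expect_equal(nrow(res$table), 0)
})
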