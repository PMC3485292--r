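# PLS-discriminant and KNN classification, train/test protocol.

separable_toy <- function(seed = 1, n1 = 6, n2 = 6, n_genes = 10, gap = 6) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * (n1 + n2)), n_genes)
  m[, (n1 + 1):(n1 + n2)] <- m[, (n1 + 1):(n1 + n2)] + gap
  rownames(m) <- sprintf("g%05d", seq_len(n_genes))
  colnames(m) <- sprintf("s%03d", seq_len(n1 + n2))
  list(m = m, labels = rep(c("Class1", "Class2"), c(n1, n2)))
}

test_that("the first PLS weight vector is proportional to X'y", {
  toy <- separable_toy(seed = 2)
  model <- train_da(toy$m, toy$labels, n_components = 1, anova_alpha = 0.5)
  X <- t(toy$m[model$selected, ])
  Xc <- sweep(X, 2, colMeans(X))
  y <- ifelse(toy$labels == "Class2", 1, -1)
  yc <- y - mean(y)
  w_direct <- crossprod(Xc, yc)
  w_direct <- w_direct / sqrt(sum(w_direct^2))
  w_model <- model$pls$W[, 1]
  expect_equal(abs(sum(w_direct * w_model)), 1, tolerance = 1e-10)
})

test_that("DA separates a linearly separable toy and re-predicts its training labels", {
  toy <- separable_toy(seed = 3)
  model <- train_da(toy$m, toy$labels, n_components = 2)
  rep <- predict_da(model, toy$m, reference = toy$labels)
  expect_equal(rep$accuracy, 1)
  expect_error(train_da(toy$m, toy$labels, n_components = 0), "n_components")
})

test_that("DA predictions are symmetric under class relabeling and duplicate-safe", {
  toy <- separable_toy(seed = 4)
  m1 <- train_da(toy$m, toy$labels, n_components = 1)
  swapped <- ifelse(toy$labels == "Class1", "Class2", "Class1")
  m2 <- train_da(toy$m, swapped, n_components = 1)
  p1 <- predict_da(m1, toy$m)$predicted
  p2 <- predict_da(m2, toy$m)$predicted
  expect_true(all(p1 != p2))
  dup <- toy$m[, c(1, 1)]
  colnames(dup) <- c("a", "b")
  pd <- predict_da(m1, dup)$predicted
  expect_identical(unname(pd[1]), unname(pd[2]))
  expect_error(predict_da(m1, toy$m[-(1:3), ]), "lacks model genes")
})

test_that("DA with one component agrees with the centroid rule on its scores", {
  toy <- separable_toy(seed = 5, gap = 8)
  model <- train_da(toy$m, toy$labels, n_components = 1)
  scores <- sweep(t(toy$m[model$selected, ]), 2, model$gene_means) %*% model$pls$R
  centers <- tapply(scores[, 1], toy$labels, mean)
  centroid <- names(centers)[apply(abs(outer(scores[, 1], centers, "-")), 1,
                                   which.min)]
  expect_identical(unname(predict_da(model, toy$m)$predicted),
                   unname(centroid))
})

test_that("KNN matches an exhaustive-distance oracle on a 2-D toy", {
  train <- matrix(c(0, 0, 1, 0, 0, 1, 5, 5, 6, 5, 5, 6), nrow = 2)
  rownames(train) <- c("g1", "g2")
  colnames(train) <- sprintf("t%d", 1:6)
  labels <- rep(c("A", "B"), each = 3)
  test <- matrix(c(0.2, 0.4, 5.1, 4.9, 2.6, 2.4), nrow = 2)
  rownames(test) <- c("g1", "g2")
  colnames(test) <- sprintf("u%d", 1:3)
  got <- knn_classify(train, labels, test, k = 3, scale = FALSE)$predicted
  oracle <- apply(test, 2, function(p) {
    d <- sqrt(colSums((train - p)^2))
    names(sort(table(labels[order(d)[1:3]]), decreasing = TRUE))[1]
  })
  expect_identical(unname(got), unname(oracle))
})

test_that("KNN honors k = 1 self-matches, tie-breaks by the nearest neighbor, checks k", {
  toy <- separable_toy(seed = 6)
  self <- knn_classify(toy$m, toy$labels, toy$m[, 3, drop = FALSE], k = 1)
  expect_identical(unname(self$predicted), toy$labels[3])
  # engineered 2-2 tie at k = 4: nearest single neighbor decides
  train <- matrix(c(0, 1, 2, 3), nrow = 1,
                  dimnames = list("g1", sprintf("t%d", 1:4)))
  labels <- c("A", "A", "B", "B")
  test <- matrix(1.4, 1, 1, dimnames = list("g1", "u1"))
  got <- knn_classify(train, labels, test, k = 4, scale = FALSE)
  expect_identical(unname(got$predicted), "A") # nearest is t2 (A) at 0.4
  expect_error(knn_classify(train, labels, test, k = 5), "between 1 and")
})

test_that("KNN is invariant to constant shifts and positive scaling but not Box-Cox", {
  d <- skewed_design(300, 40, 1.0, seed = 7)
  em <- gen_two_class(d)
  sp <- split_train_test(stats::setNames(em$labels, colnames(em$values)),
                         seed = 7)
  v <- em$values
  trl <- em$labels[match(sp$train, colnames(v))]
  base <- knn_classify(v[, sp$train], trl, v[, sp$test])$predicted
  shift <- knn_classify(v[, sp$train] + 11, trl, v[, sp$test] + 11)$predicted
  scale <- knn_classify(v[, sp$train] * 2.3, trl, v[, sp$test] * 2.3)$predicted
  expect_identical(base, shift)
  expect_identical(base, scale)
  # Box-Cox is nonlinear: for some seed the predictions must differ
  flips <- vapply(1:20, function(s) {
    em <- gen_two_class(skewed_design(300, 40, 1.0, seed = s))
    bc <- transform_for_normality(em)
    sp <- split_train_test(stats::setNames(em$labels, colnames(em$values)),
                           seed = s + 50)
    trl <- em$labels[match(sp$train, colnames(em$values))]
    p1 <- knn_classify(em$values[, sp$train], trl,
                       em$values[, sp$test])$predicted
    p2 <- knn_classify(bc$transformed$values[, sp$train], trl,
                       bc$transformed$values[, sp$test])$predicted
    discordance(p1, p2)$count
  }, numeric(1))
  expect_gt(sum(flips), 0)
})

test_that("the train/test split is a seeded exact partition with the stated sizes", {
  labels <- stats::setNames(rep(c("Class1", "Class2"), c(15, 8)),
                            sprintf("s%03d", 1:23))
  sp <- split_train_test(labels, n_train_c1 = 8, n_train_c2 = 5, seed = 9)
  expect_length(sp$train, 13)
  expect_length(sp$test, 10)
  expect_equal(sum(labels[sp$test] == "Class1"), 7)
  expect_equal(sum(labels[sp$test] == "Class2"), 3)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), names(labels))
  expect_identical(sp, split_train_test(labels, seed = 9))
  expect_error(split_train_test(labels[c(1:6, 16:18)], n_train_c1 = 8,
                                n_train_c2 = 5, seed = 1), "insufficient")
})

test_that("prefiltering delegates to the callers and retains planted genes", {
  em <- gen_two_class(two_class_design(1000, 15, 8, n_de = 50, effect_size = 3,
                                       noise = dist_spec("normal", c(0, 0.5)),
                                       seed = 10))
  genes_t <- prefilter_genes(em, method = "bonferroni_t", alpha = 0.01)
  expect_identical(genes_t, ttest_bonferroni(em, alpha = 0.01)$called)
  planted <- sprintf("g%05d", 1:50)
  expect_gte(length(intersect(genes_t, planted)) / length(genes_t), 0.8)
  genes_s <- prefilter_genes(em, method = "sam", target_fdr = 0.05,
                             n_perm = 100, seed = 3)
  # on a strongly separated design both filters give the same KNN output
  sp <- split_train_test(stats::setNames(em$labels, colnames(em$values)),
                         seed = 11)
  trl <- em$labels[match(sp$train, colnames(em$values))]
  tel <- em$labels[match(sp$test, colnames(em$values))]
  p_t <- knn_classify(em$values[genes_t, sp$train], trl,
                      em$values[genes_t, sp$test], reference = tel)
  p_s <- knn_classify(em$values[genes_s, sp$train], trl,
                      em$values[genes_s, sp$test], reference = tel)
  expect_identical(p_t$predicted, p_s$predicted)
  expect_equal(p_t$accuracy, 1)
  expect_error(prefilter_genes(em, alpha = 1e-300), "no genes passed")
})

test_that("both classifiers are perfect at strong separation, transformed or not", {
  for (s in 1:3) {
    em <- gen_two_class(skewed_design(200, 30, 5, seed = s))
    bc <- transform_for_normality(em)
    sp <- split_train_test(stats::setNames(em$labels, colnames(em$values)),
                           seed = s)
    trl <- em$labels[match(sp$train, colnames(em$values))]
    tel <- em$labels[match(sp$test, colnames(em$values))]
    for (v in list(em$values, bc$transformed$values)) {
      expect_equal(knn_classify(v[, sp$train], trl, v[, sp$test],
                                reference = tel)$accuracy, 1)
      model <- suppressWarnings(train_da(v[, sp$train], trl))
      expect_equal(predict_da(model, v[, sp$test],
                              reference = tel)$accuracy, 1)
    }
  }
})
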