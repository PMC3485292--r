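# Prospective two-class molecular classification: the ANOVA -> PLS ->
# linear-discriminant pipeline and the 2-class k-nearest-neighbor model,
# plus gene pre-filtering and the train/test split protocol.

#' Pre-filter genes for classifier training
#'
#' Delegates to the gene-calling module: the Bonferroni-corrected t-test
#' (default, p < 0.01) or SAM is used to eliminate genes that do not differ
#' between the classes before a classifier is trained.
#'
#' @param x Matrix or `expr_matrix`.
#' @param labels Two-class labels.
#' @param method `"bonferroni_t"` or `"sam"`.
#' @param ... Passed to the underlying caller ([ttest_bonferroni()] /
#'   [sam_two_class()]).
#' @return Character vector of retained gene ids.
#' @export
prefilter_genes <- function(x, labels = NULL,
                            method = c("bonferroni_t", "sam"), ...) {
  method <- match.arg(method)
  res <- if (method == "bonferroni_t") ttest_bonferroni(x, labels, ...)
         else sam_two_class(x, labels, ...)
  if (length(res$called) == 0L)
    stop("prefilter_genes: no genes passed the filter; relax the threshold ",
         "(alpha / target_fdr) or use a different method")
  res$called
}

# PLS1 by NIPALS on centered X (samples x genes) and centered +/-1 response.
# Returns weights W, loadings P, response loadings q, and the projection
# matrix R = W (P'W)^-1 mapping centered data to scores.
pls1_fit <- function(X, y, n_components) {
  n <- nrow(X); p <- ncol(X)
  A <- n_components
  W <- matrix(0, p, A); P <- matrix(0, p, A); qv <- numeric(A)
  Tm <- matrix(0, n, A)
  Xr <- X; yr <- y
  for (a in seq_len(A)) {
    w <- crossprod(Xr, yr)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { A <- a - 1L; break }
    w <- w / nw
    t <- Xr %*% w
    tt <- sum(t^2)
    pa <- crossprod(Xr, t) / tt
    qa <- sum(yr * t) / tt
    W[, a] <- w; P[, a] <- pa; qv[a] <- qa; Tm[, a] <- t
    Xr <- Xr - t %*% t(pa)
    yr <- yr - qa * t
  }
  if (A == 0L) stop("PLS found no informative component (X'y is zero)")
  W <- W[, seq_len(A), drop = FALSE]
  P <- P[, seq_len(A), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))
  list(W = W, P = P, q = qv[seq_len(A)], R = R, scores = Tm[, seq_len(A), drop = FALSE],
       n_components = A)
}

#' Train the PLS-discriminant classifier
#'
#' The multi-step pipeline: one-way ANOVA gene selection at `anova_alpha`,
#' partial least squares (NIPALS) dimension reduction of the centered
#' training data against the +/-1-coded class response, then a linear
#' discriminant on the component scores. For two classes the discriminant
#' is binary ("polychotomous" collapses to a single contrast).
#'
#' @param x Training matrix or `expr_matrix` (genes x samples).
#' @param labels Two-class labels.
#' @param n_components PLS components (default 3; reduced with a warning if
#'   it exceeds what the data support).
#' @param anova_alpha ANOVA selection level (default 0.01).
#' @return A `trained_classifier` of kind `"DA"`.
#' @export
train_da <- function(x, labels = NULL, n_components = 3L, anova_alpha = 0.01) {
  m <- em_values(x)
  labels <- em_labels(x, labels)
  cc <- class_columns(m, labels)
  n_components <- as.integer(n_components)
  if (n_components < 1L) stop("n_components must be >= 1")

  # one-way ANOVA F = t^2 with (1, n-2) df; select at anova_alpha
  st <- pooled_gene_stats(m, cc$i1, cc$i2)
  tt <- (st$mean2 - st$mean1) / st$se
  p <- 2 * stats::pt(-abs(tt), st$n1 + st$n2 - 2)
  p[!is.finite(tt)] <- ifelse((st$mean2 - st$mean1)[!is.finite(tt)] != 0, 0, 1)
  selected <- rownames(m)[p < anova_alpha]
  if (length(selected) == 0L)
    stop("train_da: ANOVA selected no genes at alpha = ", anova_alpha)

  X <- t(m[selected, , drop = FALSE])     # samples x genes
  y <- ifelse(labels == cc$classes[2], 1, -1)
  gene_means <- colMeans(X)
  Xc <- sweep(X, 2, gene_means)
  yc <- y - mean(y)
  max_comp <- min(length(selected), nrow(X) - 1L)
  if (n_components > max_comp) {
    warning("train_da: n_components reduced from ", n_components, " to ",
            max_comp)
    n_components <- max_comp
  }
  pls <- pls1_fit(Xc, yc, n_components)
  scores <- data.frame(pls$scores)
  names(scores) <- paste0("C", seq_len(pls$n_components))
  lda_fit <- MASS::lda(scores, grouping = factor(labels, levels = cc$classes))
  structure(list(kind = "DA", classes = cc$classes, selected = selected,
                 gene_means = gene_means, pls = pls, lda = lda_fit,
                 n_components = pls$n_components, anova_alpha = anova_alpha),
            class = "trained_classifier")
}

#' Predict classes with a trained PLS-discriminant model
#'
#' Projects test samples onto the training PLS components and applies the
#' linear discriminant; deterministic.
#'
#' @param model A [train_da()] result.
#' @param x Test matrix or `expr_matrix`; its genes must include every
#'   selected training gene.
#' @param reference Optional true labels for accuracy reporting.
#' @return A `classification_report`: `predicted`, `reference`, `scores`
#'   (per-sample component scores).
#' @export
predict_da <- function(model, x, reference = NULL) {
  stopifnot(inherits(model, "trained_classifier"), model$kind == "DA")
  m <- em_values(x)
  missing <- setdiff(model$selected, rownames(m))
  if (length(missing))
    stop("predict_da: test matrix lacks model genes: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  X <- t(m[model$selected, , drop = FALSE])
  Xc <- sweep(X, 2, model$gene_means)
  scores <- Xc %*% model$pls$R
  sc <- data.frame(scores)
  names(sc) <- paste0("C", seq_len(model$n_components))
  pred <- as.character(stats::predict(model$lda, sc)$class)
  classification_report(pred, colnames(m), reference, scores = scores)
}

#' k-nearest-neighbor two-class prediction
#'
#' Euclidean distances over the (z-scored, by training statistics) gene
#' space; majority vote among the k nearest training samples. A tied vote
#' (e.g. 2-2 at the default k = 4) is decided by the label of the single
#' nearest neighbor — deterministic and distance-respecting.
#'
#' @param train Matrix or `expr_matrix` of training samples.
#' @param train_labels Class labels for the training samples.
#' @param test Matrix or `expr_matrix` of test samples over the same genes.
#' @param k Neighbors (default 4).
#' @param scale Z-score genes by training mean/sd before computing
#'   distances (default TRUE).
#' @param reference Optional true test labels.
#' @return A `classification_report` with per-sample nearest-neighbor
#'   distances in `scores`.
#' @export
knn_classify <- function(train, train_labels = NULL, test, k = 4L,
                         scale = TRUE, reference = NULL) {
  mtr <- em_values(train)
  labels <- em_labels(train, train_labels)
  mte <- em_values(test)
  if (!identical(rownames(mtr), rownames(mte))) {
    if (!setequal(rownames(mtr), rownames(mte)))
      stop("knn_classify: train and test gene sets differ")
    mte <- mte[rownames(mtr), , drop = FALSE]
  }
  k <- as.integer(k)
  if (k < 1L || k > ncol(mtr))
    stop("knn_classify: k must be between 1 and the number of training samples")
  if (scale) {
    mu <- rowMeans(mtr)
    sdv <- apply(mtr, 1, stats::sd)
    sdv[sdv == 0] <- 1 # constant training genes carry no distance signal
    mtr <- (mtr - mu) / sdv
    mte <- (mte - mu) / sdv
  }
  pred <- character(ncol(mte))
  nn_dist <- numeric(ncol(mte))
  for (j in seq_len(ncol(mte))) {
    d <- sqrt(colSums((mtr - mte[, j])^2))
    ord <- order(d, seq_along(d)) # index tie-break: deterministic
    nn <- ord[seq_len(k)]
    votes <- table(labels[nn])
    winners <- names(votes)[votes == max(votes)]
    pred[j] <- if (length(winners) == 1L) winners else labels[ord[1L]]
    nn_dist[j] <- d[ord[1L]]
  }
  classification_report(pred, colnames(mte), reference,
                        scores = stats::setNames(nn_dist, colnames(mte)))
}

#' Seeded train/test split by class
#'
#' Random selection without replacement of `n_train_c1` samples of the
#' first class and `n_train_c2` of the second into the training set; all
#' remaining samples form the test set (default 8 + 5 train, leaving
#' 7 + 3 test for the 15 + 8 design).
#'
#' @param labels Class labels, named by sample id (or names taken from an
#'   `expr_matrix` via its columns).
#' @param n_train_c1,n_train_c2 Training samples per class (classes in
#'   sorted label order).
#' @param seed Integer seed.
#' @return List with `train` and `test` sample ids (a partition).
#' @export
split_train_test <- function(labels, n_train_c1 = 8L, n_train_c2 = 5L, seed) {
  if (is.null(names(labels)))
    names(labels) <- sprintf("s%03d", seq_along(labels))
  classes <- check_two_classes(labels)
  ids1 <- names(labels)[labels == classes[1]]
  ids2 <- names(labels)[labels == classes[2]]
  if (length(ids1) < n_train_c1 || length(ids2) < n_train_c2 ||
      length(ids1) + length(ids2) <= n_train_c1 + n_train_c2)
    stop("split_train_test: insufficient samples for the requested split")
  set_call_seed(seed)
  train <- c(sample(ids1, n_train_c1), sample(ids2, n_train_c2))
  test <- setdiff(names(labels), train)
  list(train = train, test = test)
}

classification_report <- function(predicted, sample_ids, reference = NULL,
                                  scores = NULL) {
  out <- list(predicted = stats::setNames(as.character(predicted), sample_ids),
              reference = if (is.null(reference)) NULL
                          else stats::setNames(as.character(reference), sample_ids),
              scores = scores)
  if (!is.null(reference))
    out$accuracy <- mean(out$predicted == out$reference)
  class(out) <- "classification_report"
  out
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification_report: %d samples", length(x$predicted)))
  if (!is.null(x$accuracy)) cat(sprintf(", accuracy %.1f%%", 100 * x$accuracy))
  cat("\n")
  tab <- table(x$predicted)
  cat(" ", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
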