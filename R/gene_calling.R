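# Two-class differential-expression callers, implemented from their
# defining procedures: Bonferroni-corrected pooled t, SAM permutation
# analysis, Kruskal-Wallis with Benjamini-Hochberg correction, and an
# empirical-Bayes moderated t with closed-form hyperparameter estimation.
# Each caller returns a gene_call_result with the per-gene statistics, the
# p-values where defined, the called gene-id set and every parameter that
# influenced the call (including the seed for SAM).

gene_call_result <- function(method, statistic, p_raw, p_adjusted, called,
                             params, notes = character(0)) {
  structure(list(method = method, statistic = statistic, p_raw = p_raw,
                 p_adjusted = p_adjusted, called = called, params = params,
                 notes = notes),
            class = "gene_call_result")
}

#' @export
print.gene_call_result <- function(x, ...) {
  cat(sprintf("%s: %d of %d genes called\n", x$method, length(x$called),
              length(x$statistic)))
  ps <- vapply(x$params, function(p) paste(format(p), collapse = ","),
               character(1))
  cat("  params:", paste(names(ps), ps, sep = " = ", collapse = ", "), "\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# Split a labeled matrix into the two class-column index sets, ordered by
# the (sorted) class names so results do not depend on label order.
class_columns <- function(m, labels) {
  classes <- check_two_classes(labels)
  list(classes = classes,
       i1 = which(labels == classes[1]),
       i2 = which(labels == classes[2]))
}

# Vectorized per-gene two-sample statistics: class means, pooled variance,
# pooled standard error (as used by both the t-test and SAM).
pooled_gene_stats <- function(m, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(m[, i1, drop = FALSE])
  m2 <- rowMeans(m[, i2, drop = FALSE])
  ss1 <- rowSums((m[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((m[, i2, drop = FALSE] - m2)^2)
  s2 <- (ss1 + ss2) / (n1 + n2 - 2)
  list(n1 = n1, n2 = n2, mean1 = m1, mean2 = m2, pooled_var = s2,
       se = sqrt(s2 * (1 / n1 + 1 / n2)))
}

#' Bonferroni-corrected two-sample t-test gene calling
#'
#' Two-sided unpaired Student's t per gene (pooled variance by default,
#' Welch via `var_equal = FALSE`); a gene is called when the
#' Bonferroni-adjusted p-value is below `alpha`.
#'
#' Zero within-class-variance genes: when the class means differ the
#' statistic is +/-Inf and p = 0 (the gene is called); when the gene is
#' entirely constant it is excluded and noted.
#'
#' @param x Expression matrix (genes x samples) or `expr_matrix`.
#' @param labels Two-class sample labels (taken from `x` when attached).
#' @param alpha Familywise level (default 0.01).
#' @param var_equal Pooled-variance t (default) or Welch.
#' @return A `gene_call_result`.
#' @export
ttest_bonferroni <- function(x, labels = NULL, alpha = 0.01, var_equal = TRUE) {
  m <- em_values(x)
  labels <- em_labels(x, labels)
  cc <- class_columns(m, labels)
  st <- pooled_gene_stats(m, cc$i1, cc$i2)
  delta <- st$mean2 - st$mean1
  if (var_equal) {
    tt <- delta / st$se
    df <- rep(st$n1 + st$n2 - 2, nrow(m))
  } else {
    v1 <- rowSums((m[, cc$i1, drop = FALSE] - st$mean1)^2) / (st$n1 - 1)
    v2 <- rowSums((m[, cc$i2, drop = FALSE] - st$mean2)^2) / (st$n2 - 1)
    se2 <- v1 / st$n1 + v2 / st$n2
    tt <- delta / sqrt(se2)
    df <- se2^2 / ((v1 / st$n1)^2 / (st$n1 - 1) + (v2 / st$n2)^2 / (st$n2 - 1))
  }
  zero_se <- !is.finite(tt)
  notes <- character(0)
  if (any(zero_se)) {
    tt[zero_se] <- ifelse(delta[zero_se] != 0, sign(delta[zero_se]) * Inf,
                          NA_real_)
    excluded <- sum(is.na(tt[zero_se]))
    notes <- sprintf("%d zero-variance gene(s): %d with mean shift called at p = 0, %d constant excluded",
                     sum(zero_se), sum(zero_se) - excluded, excluded)
  }
  p <- 2 * stats::pt(-abs(tt), df)
  p[is.infinite(tt)] <- 0
  p_adj <- pmin(p * nrow(m), 1)
  called <- rownames(m)[!is.na(p_adj) & p_adj < alpha]
  gene_call_result("ttest_bonferroni", stats::setNames(tt, rownames(m)),
                   stats::setNames(p, rownames(m)),
                   stats::setNames(p_adj, rownames(m)), called,
                   params = list(alpha = alpha, var_equal = var_equal,
                                 m = nrow(m)),
                   notes = notes)
}

## ---- SAM -------------------------------------------------------------------

# SAM relative difference d_i = (mean2 - mean1) / (s_i + s0) with the
# pooled-SE gene scatter s_i.
sam_d <- function(m, i1, i2, s0) {
  st <- pooled_gene_stats(m, i1, i2)
  (st$mean2 - st$mean1) / (st$se + s0)
}

# Fudge-factor selection following the original recipe: choose s0 among
# percentile candidates of {s_i} so that the coefficient of variation of
# the d-spread (MAD) across s-quantile windows is minimized.
sam_select_s0 <- function(d_num, s, candidates = seq(0, 1, by = 0.05),
                          n_windows = 100L) {
  n_windows <- min(n_windows, max(2L, floor(length(s) / 10)))
  qs <- stats::quantile(s, probs = seq(0, 1, length.out = n_windows + 1L),
                        names = FALSE)
  win <- findInterval(s, qs, rightmost.closed = TRUE, all.inside = TRUE)
  cv <- vapply(candidates, function(alpha) {
    s0 <- stats::quantile(s, alpha, names = FALSE)
    dd <- d_num / (s + s0)
    v <- vapply(split(dd, win), function(z) stats::mad(z), numeric(1))
    v <- v[is.finite(v) & v > 0]
    if (length(v) < 2) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  alpha_hat <- candidates[which.min(cv)]
  list(s0 = stats::quantile(s, alpha_hat, names = FALSE),
       percentile = alpha_hat)
}

# All (or n_perm sampled) two-class label permutations as index matrices;
# falls back to full enumeration when the space is small.
sam_permutations <- function(n, n1, n_perm, seed) {
  total <- choose(n, n1)
  if (total <= n_perm) {
    idx <- utils::combn(n, n1)
    return(list(i1 = idx, enumerated = TRUE))
  }
  set_call_seed(seed)
  idx <- replicate(n_perm, sample.int(n, n1))
  list(i1 = idx, enumerated = FALSE)
}

#' Significance analysis of microarrays (two-class, unpaired)
#'
#' The permutation-based SAM procedure: regularized relative difference
#' d_i = (mean2 - mean1)/(s_i + s0), expected order statistics from label
#' permutations, and a delta threshold chosen as the largest call set whose
#' estimated median FDR is at or below `target_fdr` (default 0, the
#' stringent published setting).
#'
#' @param x Matrix or `expr_matrix`.
#' @param labels Two-class labels.
#' @param target_fdr Target median FDR (default 0).
#' @param n_perm Label permutations (default 1000); the full enumeration is
#'   used instead whenever it is at most `n_perm`.
#' @param seed Integer seed for the permutation draw.
#' @param s0_method `"cv_min"` (the original coefficient-of-variation
#'   recipe) or `"fixed_percentile"` (the 5th percentile of s_i).
#' @param pi0 Proportion of null genes assumed in the FDR estimate
#'   (default 1, conservative).
#' @param fdr_estimator `"median"` (the classic median count of falsely
#'   called genes across permutations, default) or `"mean"`. The median is
#'   a coarse estimator in the far tail: at target 0 it admits call sets
#'   whose cutoffs more than half of the permutations never reach, so a
#'   handful of extreme null genes can be called; the mean variant is
#'   stricter there.
#' @return A `gene_call_result`; `params` records s0, delta, the estimated
#'   FDR, permutation count and seed.
#' @export
sam_two_class <- function(x, labels = NULL, target_fdr = 0, n_perm = 1000L,
                          seed = 1L, s0_method = c("cv_min", "fixed_percentile"),
                          pi0 = 1, fdr_estimator = c("median", "mean")) {
  s0_method <- match.arg(s0_method)
  fdr_estimator <- match.arg(fdr_estimator)
  m <- em_values(x)
  labels <- em_labels(x, labels)
  cc <- class_columns(m, labels)
  st <- pooled_gene_stats(m, cc$i1, cc$i2)
  d_num <- st$mean2 - st$mean1
  s <- st$se
  s0 <- if (s0_method == "cv_min") sam_select_s0(d_num, s)$s0
        else stats::quantile(s, 0.05, names = FALSE)
  d <- d_num / (s + s0)

  n <- ncol(m)
  perms <- sam_permutations(n, st$n1, n_perm, seed)
  B <- ncol(perms$i1)
  dstar <- matrix(0, nrow = nrow(m), ncol = B)
  all_idx <- seq_len(n)
  for (b in seq_len(B)) {
    i1 <- perms$i1[, b]
    dstar[, b] <- sam_d(m, i1, setdiff(all_idx, i1), s0)
  }
  dstar <- apply(dstar, 2, sort)        # per-permutation order statistics
  dbar <- rowMeans(dstar)               # expected order statistics

  ord <- order(d)
  d_sorted <- d[ord]
  dev <- d_sorted - dbar

  cuts_for_delta <- function(delta) {
    up_ok <- dev >= delta
    lo_ok <- dev <= -delta
    list(cutup = if (any(up_ok)) min(d_sorted[up_ok]) else Inf,
         cutlow = if (any(lo_ok)) max(d_sorted[lo_ok]) else -Inf)
  }
  eval_delta <- function(delta) {
    ct <- cuts_for_delta(delta)
    called <- d >= ct$cutup | d <= ct$cutlow
    n_called <- sum(called)
    false_per_perm <- colSums(dstar >= ct$cutup) + colSums(dstar <= ct$cutlow)
    avg <- if (fdr_estimator == "median") stats::median(false_per_perm)
           else mean(false_per_perm)
    fdr <- if (n_called == 0) 0 else min(1, pi0 * avg / n_called)
    list(delta = delta, called = called, n_called = n_called, fdr = fdr,
         cutup = ct$cutup, cutlow = ct$cutlow)
  }

  # Candidate deltas where the call set changes, scanned from the most
  # stringent (largest delta, empty set) toward the most liberal; the scan
  # stops at the first delta whose estimated FDR exceeds the target, so an
  # isolated dip of the noisy FDR curve deep in the liberal range cannot
  # be selected. A coarse quantile sweep brackets the stopping point, then
  # the bracket is rescanned at full resolution.
  descend <- function(cands) { # cands sorted decreasing
    last_pass <- NULL
    for (delta in cands) {
      ev <- eval_delta(delta)
      if (ev$fdr > target_fdr) return(list(pass = last_pass, fail = delta))
      last_pass <- ev
    }
    list(pass = last_pass, fail = NULL)
  }
  cand <- sort(unique(abs(dev)), decreasing = TRUE)
  if (length(cand) > 64L) {
    coarse <- cand[unique(round(seq(1, length(cand), length.out = 64L)))]
    res <- descend(coarse)
    if (!is.null(res$fail)) {
      from <- if (is.null(res$pass)) cand[1] else res$pass$delta
      fine <- cand[cand <= from & cand >= res$fail]
      res2 <- descend(fine)
      if (!is.null(res2$pass)) res <- res2
    }
    chosen <- res$pass
  } else {
    chosen <- descend(cand)$pass
  }
  if (is.null(chosen)) # even the most stringent cut fails: call nothing
    chosen <- list(delta = Inf, called = rep(FALSE, nrow(m)), n_called = 0,
                   fdr = 0, cutup = Inf, cutlow = -Inf)

  called <- rownames(m)[chosen$called]
  gene_call_result("sam", stats::setNames(d, rownames(m)),
                   p_raw = NULL, p_adjusted = NULL, called = called,
                   params = list(target_fdr = target_fdr,
                                 estimated_fdr = chosen$fdr,
                                 fdr_estimator = fdr_estimator,
                                 delta = chosen$delta, s0 = s0,
                                 s0_method = s0_method, pi0 = pi0,
                                 n_perm = B, enumerated = perms$enumerated,
                                 cutup = chosen$cutup, cutlow = chosen$cutlow,
                                 seed = seed),
                   notes = if (perms$enumerated)
                     "permutation space enumerated in full" else character(0))
}

## ---- Kruskal-Wallis --------------------------------------------------------

# Tie-corrected Kruskal-Wallis H for one gene, two classes, direct formula.
kw_h <- function(v, i1, i2) {
  n <- length(v)
  r <- rank(v)
  h <- 12 / (n * (n + 1)) *
    (sum(r[i1])^2 / length(i1) + sum(r[i2])^2 / length(i2)) - 3 * (n + 1)
  ties <- table(v)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) return(NA_real_) # all observations tied
  h / corr
}

#' Kruskal-Wallis gene calling with Benjamini-Hochberg correction
#'
#' Tie-corrected two-class Kruskal-Wallis H per gene with chi-square
#' (df = 1) p-values and BH step-up selection at `fdr`. Being a rank
#' statistic, the calls are invariant under any strictly monotone transform
#' of the data — including Box-Cox.
#'
#' @param x Matrix or `expr_matrix`.
#' @param labels Two-class labels.
#' @param fdr BH false-discovery-rate level (default 0.05).
#' @return A `gene_call_result`.
#' @export
kruskal_wallis_bh <- function(x, labels = NULL, fdr = 0.05) {
  m <- em_values(x)
  labels <- em_labels(x, labels)
  cc <- class_columns(m, labels)
  h <- apply(m, 1, kw_h, i1 = cc$i1, i2 = cc$i2)
  p <- stats::pchisq(h, df = 1, lower.tail = FALSE)
  p[is.na(h)] <- 1 # fully tied gene carries no rank information
  p_adj <- stats::p.adjust(p, method = "BH")
  called <- rownames(m)[p_adj < fdr]
  gene_call_result("kruskal_wallis_bh", stats::setNames(h, rownames(m)),
                   stats::setNames(p, rownames(m)),
                   stats::setNames(p_adj, rownames(m)), called,
                   params = list(fdr = fdr, m = nrow(m)))
}

## ---- moderated t -----------------------------------------------------------

# Inverse of the trigamma function by Newton iteration (monotone, so the
# iteration converges from the standard starting value).
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    x <- 0.5 + 1 / yy
    for (i in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

# Closed-form method-of-moments fit of the variance prior (d0, s0^2) on
# log s_g^2: e_g = log s_g^2 - digamma(dg/2) + log(dg/2) has
# E[e] = log s0^2 - digamma(d0/2) + log(d0/2) and
# Var[e] = trigamma(dg/2) + trigamma(d0/2).
fit_variance_prior <- function(s2, dg) {
  ok <- s2 > 0
  e <- log(s2[ok]) - digamma(dg / 2) + log(dg / 2)
  evar <- stats::var(e) - trigamma(dg / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_sq = exp(mean(e)), note = "non-positive moment estimate; prior df treated as infinite"))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq, note = NULL)
}

#' Empirical-Bayes moderated t-test gene calling
#'
#' Per-gene residual variances are shrunk toward a prior estimated across
#' genes: s_tilde_g^2 = (d0 s0^2 + dg s_g^2)/(d0 + dg), with the prior
#' degrees of freedom d0 and prior variance s0^2 obtained by closed-form
#' method of moments on log s_g^2. The moderated t uses dg + d0 degrees of
#' freedom. Calls default to raw p < alpha (the convention that produces
#' the large call counts typical of this method); BH adjustment via
#' `adjust = "BH"`.
#'
#' @param x Matrix or `expr_matrix`.
#' @param labels Two-class labels.
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param d0 Optional prior degrees-of-freedom override: 0 recovers the
#'   ordinary t exactly, Inf uses the prior variance alone.
#' @return A `gene_call_result`; `params` records d0 and s0^2.
#' @export
moderated_t <- function(x, labels = NULL, alpha = 0.05,
                        adjust = c("none", "BH"), d0 = NULL) {
  adjust <- match.arg(adjust)
  m <- em_values(x)
  labels <- em_labels(x, labels)
  cc <- class_columns(m, labels)
  st <- pooled_gene_stats(m, cc$i1, cc$i2)
  dg <- st$n1 + st$n2 - 2
  notes <- character(0)
  if (is.null(d0)) {
    prior <- fit_variance_prior(st$pooled_var, dg)
    d0 <- prior$d0
    s0_sq <- prior$s0_sq
    if (!is.null(prior$note)) notes <- prior$note
  } else {
    s0_sq <- if (d0 > 0 && is.finite(d0))
      fit_variance_prior(st$pooled_var, dg)$s0_sq
    else if (is.infinite(d0))
      fit_variance_prior(st$pooled_var, dg)$s0_sq
    else NA_real_ # d0 = 0: prior never enters
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, nrow(m))
             else if (d0 == 0) st$pooled_var
             else (d0 * s0_sq + dg * st$pooled_var) / (d0 + dg)
  tt <- (st$mean2 - st$mean1) / sqrt(s2_post * (1 / st$n1 + 1 / st$n2))
  df <- dg + d0
  p <- if (is.infinite(df)) 2 * stats::pnorm(-abs(tt))
       else 2 * stats::pt(-abs(tt), df)
  zero <- !is.finite(tt)
  if (any(zero)) {
    delta <- (st$mean2 - st$mean1)[zero]
    tt[zero] <- ifelse(delta != 0, sign(delta) * Inf, NA_real_)
    p[zero] <- ifelse(delta != 0, 0, NA_real_)
    notes <- c(notes, sprintf("%d zero-posterior-variance gene(s) handled", sum(zero)))
  }
  p_adj <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  called <- rownames(m)[!is.na(p_adj) & p_adj < alpha]
  gene_call_result("moderated_t", stats::setNames(tt, rownames(m)),
                   stats::setNames(p, rownames(m)),
                   stats::setNames(p_adj, rownames(m)), called,
                   params = list(alpha = alpha, adjust = adjust, d0 = d0,
                                 s0_sq = s0_sq, residual_df = dg),
                   notes = notes)
}

#' Dispatch a gene caller by id
#'
#' @param method One of `"ttest_bonferroni"`, `"sam"`,
#'   `"kruskal_wallis_bh"`, `"moderated_t"`.
#' @param x,labels Data and two-class labels.
#' @param ... Passed to the caller.
#' @return A `gene_call_result`.
#' @export
call_genes <- function(method = c("ttest_bonferroni", "sam",
                                  "kruskal_wallis_bh", "moderated_t"),
                       x, labels = NULL, ...) {
  method <- match.arg(method)
  switch(method,
         ttest_bonferroni = ttest_bonferroni(x, labels, ...),
         sam = sam_two_class(x, labels, ...),
         kruskal_wallis_bh = kruskal_wallis_bh(x, labels, ...),
         moderated_t = moderated_t(x, labels, ...))
}
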