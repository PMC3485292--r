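# Central-moments analysis: pooled and per-gene moment estimation with
# significance tests against a simulated standard normal.

#' Sample skewness
#'
#' Moment estimator g1 = m3 / m2^(3/2) (default) or the bias-corrected
#' G1 = g1 * sqrt(n(n-1))/(n-2).
#'
#' @param x Numeric vector.
#' @param estimator `"moment"` (g1) or `"bias_corrected"` (G1).
#' @return Skewness, or `NA` for a constant vector.
#' @export
sample_skewness <- function(x, estimator = c("moment", "bias_corrected")) {
  estimator <- match.arg(estimator)
  n <- length(x)
  if (n < 3L) stop("skewness needs n >= 3")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  g1 <- mean((x - m)^3) / m2^1.5
  if (estimator == "bias_corrected") g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g1
}

#' Sample excess kurtosis
#'
#' Moment estimator g2 = m4 / m2^2 - 3 (default) or the bias-corrected
#' G2 = ((n+1) g2 + 6) (n-1) / ((n-2)(n-3)).
#'
#' @inheritParams sample_skewness
#' @return Excess kurtosis, or `NA` for a constant vector.
#' @export
sample_excess_kurtosis <- function(x, estimator = c("moment", "bias_corrected")) {
  estimator <- match.arg(estimator)
  n <- length(x)
  if (n < 4L) stop("kurtosis needs n >= 4")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  g2 <- mean((x - m)^4) / m2^2 - 3
  if (estimator == "bias_corrected")
    g2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  g2
}

#' Standard error of skewness
#'
#' Large-sample sqrt(6/n) by default (this is the convention behind the
#' Fisher index arithmetic in the pooled-dataset tables); the exact
#' small-sample normal-theory formula via `exact = TRUE`.
#'
#' @param n Sample size.
#' @param exact Use the exact small-sample formula.
#' @return Standard error.
#' @export
se_skewness <- function(n, exact = FALSE) {
  if (n < 3) stop("n >= 3 required")
  if (!exact) return(sqrt(6 / n))
  sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
}

#' Standard error of kurtosis
#'
#' Large-sample sqrt(24/n) by default; exact small-sample formula via
#' `exact = TRUE`.
#'
#' @inheritParams se_skewness
#' @return Standard error.
#' @export
se_kurtosis <- function(n, exact = FALSE) {
  if (n < 4) stop("n >= 4 required")
  if (!exact) return(sqrt(24 / n))
  2 * se_skewness(n, exact = TRUE) * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
}

#' Fisher's index of skewness
#'
#' Sample skewness divided by its standard error sqrt(6/n); significant at
#' alpha = 0.05 when it exceeds +/- 1.96.
#'
#' @param g1 Sample skewness.
#' @param n Sample size.
#' @param exact Use the exact small-sample standard error.
#' @return The index g1 / SES.
#' @export
fisher_skewness_index <- function(g1, n, exact = FALSE) {
  g1 / se_skewness(n, exact = exact)
}

#' Fisher's index of kurtosis
#'
#' Sample excess kurtosis divided by its standard error sqrt(24/n).
#'
#' @param g2 Sample excess kurtosis.
#' @inheritParams fisher_skewness_index
#' @return The index g2 / SEK.
#' @export
fisher_kurtosis_index <- function(g2, n, exact = FALSE) {
  g2 / se_kurtosis(n, exact = exact)
}

#' First four central moments with standard errors and Fisher indices
#'
#' @param values Numeric vector, n >= 4.
#' @param estimator Skewness/kurtosis estimator, `"moment"` (default; the
#'   biased moment estimators g1, g2) or `"bias_corrected"` (G1, G2).
#' @param exact_se Use exact small-sample standard errors instead of the
#'   large-sample sqrt(6/n), sqrt(24/n).
#' @return A `moments_summary` list: `n`, `mean`, `variance` (unbiased),
#'   `sd`, `skewness`, `excess_kurtosis`, `ses`, `sek`,
#'   `fisher_skew_index`, `fisher_kurt_index`, and `degenerate` (TRUE for a
#'   constant vector, in which case skewness/kurtosis and the indices are
#'   flagged `NA` rather than propagating NaN).
#' @export
central_moments <- function(values, estimator = c("moment", "bias_corrected"),
                            exact_se = FALSE) {
  estimator <- match.arg(estimator)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("central_moments: non-finite values")
  n <- length(values)
  if (n < 4L) stop("central_moments needs n >= 4")
  mu <- mean(values)
  v <- stats::var(values)
  degenerate <- v == 0
  g1 <- if (degenerate) NA_real_ else sample_skewness(values, estimator)
  g2 <- if (degenerate) NA_real_ else sample_excess_kurtosis(values, estimator)
  ses <- se_skewness(n, exact = exact_se)
  sek <- se_kurtosis(n, exact = exact_se)
  out <- list(
    n = n, mean = mu, variance = v, sd = sqrt(v),
    skewness = g1, excess_kurtosis = g2,
    ses = ses, sek = sek,
    fisher_skew_index = if (degenerate) NA_real_ else g1 / ses,
    fisher_kurt_index = if (degenerate) NA_real_ else g2 / sek,
    estimator = estimator, degenerate = degenerate
  )
  class(out) <- "moments_summary"
  out
}

#' @export
print.moments_summary <- function(x, ...) {
  cat(sprintf("Central moments (n = %d)\n", x$n))
  cat(sprintf("  mean %.4f  variance %.4f  sd %.4f\n", x$mean, x$variance, x$sd))
  if (x$degenerate) {
    cat("  constant input: skewness/kurtosis undefined\n")
  } else {
    cat(sprintf("  skewness %.4f (Fisher index %.4g)\n",
                x$skewness, x$fisher_skew_index))
    cat(sprintf("  excess kurtosis %.4f (Fisher index %.4g)\n",
                x$excess_kurtosis, x$fisher_kurt_index))
  }
  invisible(x)
}

#' Simulate the standard-normal reference sample
#'
#' Seed-deterministic i.i.d. standard-normal draws used as the comparison
#' sample for the mean and Kolmogorov-Smirnov tests.
#'
#' @param n Number of draws (default 1e7).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_normal_reference <- function(n = 1e7, seed) {
  if (n < 2) stop("n >= 2 required")
  set_call_seed(seed)
  stats::rnorm(n)
}

#' Compare means against a reference sample
#'
#' Two-class unpaired t-test and Wilcoxon rank-sum of `values` versus the
#' (typically simulated standard normal) `reference`.
#'
#' @param values Numeric vector.
#' @param reference Numeric vector.
#' @return List with `t_p` and `wilcoxon_p`.
#' @export
mean_tests <- function(values, reference) {
  if (length(values) < 2 || length(reference) < 2) stop("both samples need n >= 2")
  t_p <- stats::t.test(values, reference)$p.value
  w_p <- stats::wilcox.test(values, reference)$p.value
  list(t_p = t_p, wilcoxon_p = w_p)
}

#' Test a variance against a null value
#'
#' Two-sided chi-square test of H0: variance = `null_variance` (the variance
#' ratio test against a theoretical unit-variance normal) with a 95%
#' chi-square confidence interval for the variance.
#'
#' @param values Numeric vector.
#' @param null_variance Null variance (default 1, the standard normal).
#' @param conf_level Confidence level for the interval.
#' @return List with `statistic` (the variance ratio s^2/sigma0^2), `f_p`
#'   (two-sided p) and `ci` (variance CI).
#' @export
variance_test <- function(values, null_variance = 1, conf_level = 0.95) {
  n <- length(values)
  if (n < 2) stop("n >= 2 required")
  s2 <- stats::var(values)
  if (s2 == 0) stop("variance_test: degenerate input (zero variance)")
  chi <- (n - 1) * s2 / null_variance
  lower_tail <- stats::pchisq(chi, df = n - 1)
  p <- 2 * min(lower_tail, 1 - lower_tail)
  a <- (1 - conf_level) / 2
  ci <- c((n - 1) * s2 / stats::qchisq(1 - a, df = n - 1),
          (n - 1) * s2 / stats::qchisq(a, df = n - 1))
  list(statistic = s2 / null_variance, f_p = min(p, 1), ci = ci)
}

# Asymptotic Kolmogorov distribution: P(sqrt(n) D > lambda), via the
# alternating series 2 sum (-1)^(k-1) exp(-2 k^2 lambda^2), truncated when
# terms drop below 1e-10.
kolmogorov_p <- function(lambda) {
  if (lambda <= 0) return(1)
  p <- 0
  for (k in 1:1000) {
    term <- 2 * (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
    p <- p + term
    if (abs(term) < 1e-10) break
  }
  min(max(p, 0), 1)
}

#' Kolmogorov-Smirnov critical value
#'
#' c(alpha)/sqrt(n) with c(alpha) = sqrt(-log(alpha/2)/2), so c(0.05) =
#' 1.3581. Strictly decreasing in n.
#'
#' @param n Sample size.
#' @param alpha Significance level.
#' @return Critical value for the one-sample KS statistic D.
#' @export
ks_critical_value <- function(n, alpha = 0.05) {
  sqrt(-log(alpha / 2) / 2) / sqrt(n)
}

#' One-sample Kolmogorov-Smirnov test against an arbitrary CDF
#'
#' D = sup |empirical - reference|; p-value from the asymptotic Kolmogorov
#' series; critical value c(alpha)/sqrt(n).
#'
#' @param values Numeric vector, n >= 1.
#' @param reference_cdf Vectorized CDF function (default standard normal).
#' @param alpha Significance level for the critical value.
#' @return List with `D`, `p`, `critical` and `reject` (D > critical).
#' @export
ks_one_sample <- function(values, reference_cdf = stats::pnorm, alpha = 0.05) {
  n <- length(values)
  if (n < 1) stop("n >= 1 required")
  x <- sort(values)
  Fx <- reference_cdf(x)
  D <- max(pmax(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n))
  crit <- ks_critical_value(n, alpha)
  list(D = D, p = kolmogorov_p(sqrt(n) * D), critical = crit, reject = D > crit)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Sup-difference of the two empirical CDFs with the asymptotic p-value at
#' effective size n1 n2 / (n1 + n2).
#'
#' @param a,b Numeric vectors.
#' @param alpha Significance level (recorded; the asymptotic p is returned).
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(a, b, alpha = 0.05) {
  n1 <- as.numeric(length(a)); n2 <- as.numeric(length(b))
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  pooled <- sort(unique(c(a, b)))
  Fa <- findInterval(pooled, sort(a)) / n1
  Fb <- findInterval(pooled, sort(b)) / n2
  D <- max(abs(Fa - Fb))
  neff <- n1 * n2 / (n1 + n2)
  list(D = D, p = kolmogorov_p(sqrt(neff) * D))
}

#' Full normality report for a pooled dataset
#'
#' Runs the central-moments analysis plus the significance battery against a
#' simulated standard normal: t-test and Wilcoxon on the mean, chi-square
#' variance test, Fisher indices for skewness and kurtosis, and one- and
#' two-sample KS tests.
#'
#' @param values Numeric vector (e.g. all entries of a log2-ratio matrix).
#' @param reference Simulated standard-normal sample; generated from
#'   `reference_n` and `seed` when NULL.
#' @param reference_n Size of the simulated reference (default 1e7).
#' @param seed Seed for the simulated reference (recorded in the report).
#' @param alpha Significance level for the verdicts.
#' @param estimator Passed to [central_moments()].
#' @return A `normality_report` list with the `moments_summary`, test
#'   p-values, KS results, the per-test verdicts at `alpha`, and the
#'   seed/parameters used.
#' @export
normality_report <- function(values, reference = NULL, reference_n = 1e7,
                             seed = 1L, alpha = 0.05,
                             estimator = c("moment", "bias_corrected")) {
  estimator <- match.arg(estimator)
  if (is.null(reference)) reference <- simulate_normal_reference(reference_n, seed)
  mom <- central_moments(values, estimator = estimator)
  mt <- mean_tests(values, reference)
  vt <- variance_test(values, null_variance = 1)
  ks1 <- ks_one_sample(values, stats::pnorm, alpha = alpha)
  ks2 <- ks_two_sample(values, reference, alpha = alpha)
  zcrit <- stats::qnorm(1 - alpha / 2)
  out <- list(
    moments = mom,
    t_test_p = mt$t_p, wilcoxon_p = mt$wilcoxon_p,
    f_test_p = vt$f_p, variance_ci = vt$ci,
    ks1_statistic = ks1$D, ks1_p = ks1$p, ks1_critical = ks1$critical,
    ks2_statistic = ks2$D, ks2_p = ks2$p,
    verdict = list(
      mean_nonnormal = mt$t_p < alpha || mt$wilcoxon_p < alpha,
      variance_nonnormal = vt$f_p < alpha,
      skew_nonnormal = is.finite(mom$fisher_skew_index) &&
        abs(mom$fisher_skew_index) > zcrit,
      kurt_nonnormal = is.finite(mom$fisher_kurt_index) &&
        abs(mom$fisher_kurt_index) > zcrit,
      ks_nonnormal = ks1$reject
    ),
    alpha = alpha, seed = seed, reference_n = length(reference),
    estimator = estimator
  )
  class(out) <- "normality_report"
  out
}

#' @export
print.normality_report <- function(x, ...) {
  print(x$moments)
  cat(sprintf("  t p = %.3g, Wilcoxon p = %.3g, variance p = %.3g [%.4f, %.4f]\n",
              x$t_test_p, x$wilcoxon_p, x$f_test_p,
              x$variance_ci[1], x$variance_ci[2]))
  cat(sprintf("  KS one-sample D = %.4f (critical %.4g, p = %.3g); two-sample D = %.4f\n",
              x$ks1_statistic, x$ks1_critical, x$ks1_p, x$ks2_statistic))
  flags <- names(Filter(isTRUE, x$verdict))
  cat("  non-normal on: ", if (length(flags)) paste(flags, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' Per-gene moment table
#'
#' Per-gene standard deviation, skewness and kurtosis across samples, with
#' aggregate statistics. Kurtosis is reported plain (Gaussian = 3) for
#' comparability with the per-gene variability tables; switch to excess via
#' `kurtosis = "excess"`.
#'
#' @param x Expression matrix (genes x samples) or `expr_matrix`.
#' @param estimator Skewness/kurtosis estimator (see [central_moments()]).
#' @param kurtosis `"plain"` (default) or `"excess"`.
#' @return A `per_gene_moments` list: per-gene vectors `sd`, `skewness`,
#'   `kurtosis`; `aggregates` (mean/median/min/max/sd of each, constant
#'   genes excluded); `n_constant` and `constant_genes`.
#' @export
per_gene_moments <- function(x, estimator = c("moment", "bias_corrected"),
                             kurtosis = c("plain", "excess")) {
  estimator <- match.arg(estimator)
  kurtosis <- match.arg(kurtosis)
  m <- em_values(x)
  if (ncol(m) < 4) stop("per_gene_moments needs >= 4 samples")
  n <- ncol(m)
  mu <- rowMeans(m)
  d <- m - mu
  m2 <- rowMeans(d^2)
  m3 <- rowMeans(d^3)
  m4 <- rowMeans(d^4)
  constant <- m2 == 0
  sdv <- sqrt(m2 * n / (n - 1))
  g1 <- ifelse(constant, NA_real_, m3 / m2^1.5)
  g2 <- ifelse(constant, NA_real_, m4 / m2^2 - 3)
  if (estimator == "bias_corrected") {
    g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
    g2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  }
  kur <- if (kurtosis == "plain") g2 + 3 else g2
  agg <- function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v), median = stats::median(v), min = min(v), max = max(v),
      sd = stats::sd(v))
  }
  out <- list(
    sd = sdv, skewness = g1, kurtosis = kur,
    kurtosis_convention = kurtosis, estimator = estimator,
    aggregates = rbind(sd = agg(sdv[!constant]),
                       skewness = agg(g1), kurtosis = agg(kur)),
    n_constant = sum(constant),
    constant_genes = rownames(m)[constant]
  )
  class(out) <- "per_gene_moments"
  out
}

#' @export
print.per_gene_moments <- function(x, ...) {
  cat(sprintf("Per-gene moments (%d genes, kurtosis convention: %s)\n",
              length(x$sd), x$kurtosis_convention))
  print(round(x$aggregates, 4))
  if (x$n_constant > 0)
    cat(sprintf("  %d constant gene(s) excluded from aggregates\n", x$n_constant))
  invisible(x)
}
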