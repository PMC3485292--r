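# Independent oracles used across the suite. These are deliberately
# written as direct textbook formulas (loops, sums, enumeration), separate
# from the package's vectorized implementations.

# Direct central-moment formulas.
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  list(mean = mu, variance = sum((x - mu)^2) / (n - 1),
       skewness = m3 / m2^1.5, excess_kurtosis = m4 / m2^2 - 3)
}

# Two-sample KS statistic by direct sup over the pooled support.
oracle_ks2 <- function(a, b) {
  grid <- sort(c(a, b))
  max(abs(vapply(grid, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# assignments of the pooled ranks to group 1.
oracle_wilcoxon_exact <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(r), n1)
  w_null <- apply(combs, 2, function(i) sum(r[i]))
  p_low <- mean(w_null <= w_obs)
  p_high <- mean(w_null >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# Tie-corrected Kruskal-Wallis H by the direct textbook formula.
oracle_kw_h <- function(v, g) {
  n <- length(v)
  r <- rank(v)
  groups <- split(r, g)
  h <- 12 / (n * (n + 1)) * sum(vapply(groups, function(ri)
    sum(ri)^2 / length(ri), numeric(1))) - 3 * (n + 1)
  tie_counts <- table(v)
  h / (1 - sum(tie_counts^3 - tie_counts) / (n^3 - n))
}

# Numerical moments of a registered family by adaptive quadrature over the
# full support (infinite limits are handled by integrate's transformation,
# so no tail mass is truncated).
oracle_family_moment <- function(fam, par, k, center = 0) {
  sup <- fam$support(par)
  stats::integrate(function(x) (x - center)^k * fam$dens(x, par),
                   sup[1], sup[2], rel.tol = 1e-12,
                   subdivisions = 5000L)$value
}

# Empirical standard error of a statistic by block splitting: the SE of
# the full-sample statistic approximated from independent blocks.
block_se <- function(x, stat, n_blocks = 100L) {
  blocks <- split(x, rep(seq_len(n_blocks), length.out = length(x)))
  stats::sd(vapply(blocks, stat, numeric(1))) / sqrt(n_blocks)
}

# The canonical skewed study condition used across sensitivity tests.
skewed_design <- function(n_genes, n_de, effect_size, seed,
                          n_class1 = 15L, n_class2 = 8L) {
  two_class_design(n_genes, n_class1, n_class2, n_de = n_de,
                   effect_size = effect_size,
                   noise = skewed_noise_spec(), seed = seed)
}
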