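---
title: "Distribution diagnostics and distribution-sensitivity analysis for expression matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution diagnostics and distribution-sensitivity analysis for expression matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most downstream machinery of a translational expression study — t-tests,
empirical-Bayes linear models, discriminant classifiers — is predicated,
explicitly or not, on the data being approximately Gaussian. Log2-ratio
cancer expression matrices are not: pooled across genes and samples they
show small but (at ~10^7 values) overwhelmingly significant skewness and
excess kurtosis, and individual genes show far wider departures. `exprdist`
provides (i) the diagnostics that establish such departures, (ii) a
Box-Cox normalization that changes *only* the distribution shape, and
(iii) the sensitivity machinery that measures how much gene calling, term
enrichment and prospective classification move when the shape moves. The
null hypothesis of the sensitivity design is that a "robust" or
"distribution-free" method should not care.

## Data model and preprocessing

The analyzed object is a genes x samples matrix of log2 ratios
("log2-subtracted" data): normalized linear-scale tumor intensities are
log2-converted and the log2 of an averaged (linear scale first, then log2
— `build_reference()`) normal-tissue reference profile is subtracted
(`log_subtract()`). Alignment between tumor and reference genes is by id,
and a mismatch is an error rather than a silent positional match;
`align_genes()` is the explicit reordering step. `recenter()` removes the
grand mean (normalization pipelines leave a nonzero default mean, around 7
on raw RMA output); recentering is idempotent and exactly preserves
variance, skewness and kurtosis. Averaging replicate reference profiles
before log conversion is the default because that is the convention of the
ratio pipelines this emulates; the log-then-average order is available via
a flag for sensitivity checks, and by Jensen's inequality it is never
larger.

## Central-moments diagnostics

`central_moments()` reports mean, unbiased variance, skewness and excess
kurtosis. The default estimators are the plain moment ratios g1 =
m3/m2^(3/2) and g2 = m4/m2^2 - 3; these are what the large-n Fisher-index
arithmetic in the pooled tables implies, so they are the default, with the
bias-corrected G1/G2 behind `estimator = "bias_corrected"`. Standard
errors default to the large-sample sqrt(6/n) and sqrt(24/n) (again the
convention the index arithmetic uses); the exact small-sample normal
formulas sit behind `exact_se = TRUE`. Fisher's indices — the moment over
its standard error, compared to ±1.96 at α = 0.05 — are the headline
statistics: at n ≈ 9.8 × 10^6 pooled features a skewness of −1.64 gives an
index of −2.1 × 10^3, three orders of magnitude beyond the threshold.

"Kurtosis" is never reported bare: pooled reports use *excess* kurtosis
(Gaussian = 0) and the per-gene table uses *plain* kurtosis (Gaussian = 3)
for comparability with the per-gene variability convention; every field
and argument names its convention.

The significance battery (`normality_report()`) compares against a
simulated standard normal: unpaired t and Wilcoxon rank-sum for the mean,
a two-sided chi-square test (with 95% CI) for the variance against 1, and
one- and two-sample Kolmogorov-Smirnov tests. The one-sample KS p-value
uses the asymptotic Kolmogorov series 2Σ(−1)^(k−1)exp(−2k²λ²) truncated
when terms fall below 1e−10, and the critical value c(α)/√n with c(0.05) =
1.3581. The simulated reference defaults to 10^7 draws with its seed
recorded in every report. A true normal sampler at that size has |skewness|
within a few times sqrt(6/n) ≈ 0.0008; published "simulated normal"
references with printed skewness near −0.025 at n = 10^7 are tens of
standard errors from that and cannot be reproduced by a correct sampler,
so no such reference values are asserted anywhere in the package.

## The candidate-family catalog

Eight families cover the shapes log2-ratio data takes: normal, logistic,
Laplace, hyperbolic secant (kurtotic), three-parameter log-logistic,
four-parameter Dagum and Burr XII (β-prime relatives, skewed), and the
four-parameter Johnson SU (skew + kurtosis, natural for logarithmic data).
Parameterizations follow common fitting-software conventions and each
family documents density, CDF, quantile and sampler; `register_family()`
lets a user plug further families into the same fitting and ranking code.
The hyperbolic secant uses f(x) = sech(π(x−μ)/(2s))/(2s), so the standard
member has unit variance and density 1/(2s) at its location. Johnson SU
sampling is exact via ξ + λ·sinh((Z−γ)/δ); the shifted-support families
sample by inverse CDF.

Fitting is maximum likelihood with L-BFGS-B under box constraints, from
moment/quantile starting values, with up to five jittered restarts before
a fit is flagged non-convergent (flagged fits are excluded from ranking
with a recorded reason, not silently dropped). Location starts for the
shifted-support families sit just below the sample minimum at an
IQR-based offset — a range-based offset is dragged out by heavy right
tails and can park the optimizer in a local optimum. Goodness of fit is
the one-sample KS test of the data against the fitted CDF at α = 0.05 on
the full sample (Freedman-Diaconis histograms, 2·IQR·n^(−1/3) with a
Scott's-rule fallback at zero IQR, are for reporting only). Ranking is by
ascending KS statistic; statistics within 1e−4 are ties, broken by the PP
then QQ mean absolute deviation from the identity line, then family name,
so the order is fully deterministic.

## Box-Cox normalization

`transform_for_normality()` is the uniform monotone transform at the heart
of the sensitivity design: shift by c = max(0, 1e−6·range − min) (log
ratios are signed, and the power transform needs positivity — the shift
choice is ours, recorded in the result), select λ by profile maximum
likelihood on a [−3, 3] grid in steps of 0.01 with local refinement, apply
((x+c)^λ − 1)/λ (log at λ = 0), recenter to zero grand mean, and attach a
repeated central-moments analysis as the before/after verification. The
transform is fit once on the pooled matrix — the experiment-level
convention — with a per-gene mode behind a flag. Strict monotonicity for
every λ is what makes rank statistics exactly invariant under it; that
invariance is asserted bitwise in the tests.

## Gene calling

The four callers are implemented from their defining procedures, not
wrapped from other packages (those serve as cross-check oracles in the
test suite):

* **Bonferroni t** — pooled-variance unpaired t per gene (Welch behind a
  flag), called at p·m < α with α = 0.01. Genes with zero within-class
  variance but differing means get a signed infinite statistic and p = 0;
  fully constant genes are excluded, both logged.
* **SAM** — d = (mean2 − mean1)/(s + s0) with the pooled-SE scatter s; s0
  chosen as the percentile of {s} minimizing the coefficient of variation
  of the windowed MAD of d (the original recipe; a fixed 5th percentile is
  available). Expected order statistics come from label permutations
  (default 1,000; the space is enumerated in full when it is smaller).
  The Δ threshold is the most liberal one reachable from the stringent end
  without the estimated FDR exceeding the target — a monotonized scan, so
  an isolated dip of the noisy FDR curve cannot be selected. The FDR is
  π0 · (median permutation count beyond the cuts)/(genes called), π0 = 1.
  The median is a coarse far-tail estimator: at target FDR = 0 it can
  admit one to a few extreme null genes whose cuts more than half of the
  permutations never reach; the `mean` estimator (configurable) is strict
  there. Both behaviors are pinned in the tests.
* **Kruskal-Wallis + BH** — tie-corrected H with chi-square (df = 1)
  p-values and Benjamini-Hochberg selection at FDR 0.05. As a rank
  statistic it is exactly invariant under Box-Cox — the mechanism behind
  near-total overlap of its parent and transformed gene lists.
* **Moderated t** — per-gene variances shrunk toward a prior,
  s̃² = (d0·s0² + dg·s²)/(d0 + dg), with (d0, s0²) estimated by closed-form
  method of moments on log s² (trigamma inversion by Newton iteration);
  t on dg + d0 degrees of freedom. d0 = 0 recovers the ordinary t exactly
  and d0 = ∞ uses the prior alone (both exposed for verification). Calls
  default to raw p < 0.05 — the convention that produces this method's
  characteristically large call counts — with BH behind a flag.

## Enrichment

Over-representation of a called list against a user-supplied (GMT)
annotation is the one-sided hypergeometric upper tail per term, Bonferroni
over tested terms, called at corrected p < 0.01. The background defaults
to all genes on the matrix (configurable; web annotation tools differ here
and published analyses rarely say which background they used). The EASE
one-hit penalty is available behind a flag for comparability with
DAVID-style scores.

## Classification

Two prospective classifiers over a seeded train/test protocol
(`split_train_test()`, default 8 + 5 training and 7 + 3 held-out samples
from a 15 + 8 two-class set):

* **PLS-DA** — one-way ANOVA gene selection at α = 0.01, NIPALS PLS (the
  first weight vector is X'y normalized — asserted against that identity),
  default 3 components (reduced with a warning when the data cannot
  support them), then a linear discriminant on the component scores. For
  two classes the "polychotomous" discriminant collapses to a single
  binary contrast.
* **KNN** — Euclidean distances over genes z-scored by training statistics
  (raw scale behind a flag), majority vote among k = 4 neighbors. A 2–2
  tie is decided by the single nearest neighbor: deterministic and
  distance-respecting. Distance ties break by sample index.

KNN is invariant to global shifts and positive scalings of the expression
values, but not to Box-Cox: the transform is monotone, not affine, so
Euclidean geometry is not preserved. That is the core classification
finding this package operationalizes, and the tests exhibit synthetic
datasets where parent and transformed predictions differ for both
classifiers.

## The synthetic study conditions

The generator module is first-class code: it produces every input the
pipeline consumes. The canonical non-Gaussian condition is Johnson SU
noise with (γ, δ, ξ, λ) = (−0.6, 1.6, 0, 1) — skewness 0.98, excess
kurtosis 4.5, variance 0.70 — chosen once to sit inside the pooled-moment
ranges reported for real log2-subtracted cancer sets (skewness 0.2–0.8 in
magnitude, excess kurtosis 1.5–5.7, variance 0.7–1.1) and exposed as
`skewed_noise_spec()`. Pooled analyses use 180 samples (the harmonized
cohort size of the large public sets); the two-class design defaults to
15 + 8 samples, the low-grade-glioma-like configuration implied by the
8 + 5 / 7 + 3 classification split (an 11 + 8 variant, matching the other
published description of that cohort, is equally expressible — the two
printed descriptions disagree and the generator asserts neither).
Differential expression is a mean shift on the first `n_de` genes;
gene-calling demonstrations use 100 planted genes at 2.5 log2 units
(power for a Bonferroni filter at 13–23 samples), classification
sensitivity uses a moderate 1.0–1.5 log2 units — at 5σ separation both
classifiers are perfect on parent and transformed data alike, and the
transform's influence is visible only near the decision boundary, which
is exactly the regime the sensitivity design probes.

What the generator does *not* emulate: gene-gene correlation, per-gene
variance heterogeneity beyond what the noise family provides, batch or
array effects, and mixture-shaped single-gene distributions. Passing tests
therefore demonstrate the *mechanisms* (rank invariance, distance
non-invariance, estimator behavior), not effect sizes on any particular
real cohort.

## Numerical choices and degenerate inputs

Seeds are explicit arguments everywhere randomness enters (generators,
permutations, splits, the simulated reference) and are recorded in every
report; reports serialize to JSON with full-precision numbers and the
parameters verbatim. Constant vectors: variance 0 with skewness/kurtosis
flagged undefined (`NA` plus a `degenerate` flag), never NaN propagation;
constant genes are excluded from per-gene aggregates and counted. The
Kolmogorov series truncates below 1e−10; trigamma inversion iterates
Newton to 1e−10 relative; the Box-Cox grid is [−3, 3] step 0.01 with
golden-section refinement between neighbors. Problem sizes in the shipped
analyses and tests (2,000 × 180 pooled, 5,000 × 180 for the per-gene
anchors, 10^5 for parameter recovery, 10^6 for moment convergence,
100–1,000 SAM permutations) were chosen so each stage demonstrates its
statistical property at comfortable margins.

## Known limitations

The catalog implements eight families, not the dozens a commercial
fitting suite scans — the registry accepts plugins. KS critical values
use the true sample n; published tables whose critical values imply a
different effective n are not reproduced. Multi-class designs, paired
designs, cross-validated model selection and probabilistic classifier
outputs are out of scope, as are normalization algorithms upstream of the
log2-ratio matrix (RMA/DChip) and live GO/KEGG retrieval — enrichment
runs on user- or generator-supplied annotation tables.
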