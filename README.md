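# exprdist

Distribution diagnostics and distribution-sensitivity analysis for gene
expression matrices.

## The problem

Parametric gene-expression analytics — t-tests, empirical-Bayes linear
models, discriminant classifiers — implicitly assume the log2-ratio data
are Gaussian. Pooled cancer expression matrices are not: with millions of
features, even skewness of a few tenths is tens to thousands of standard
errors from zero, and the distributions are visibly heavy-tailed. The
practical question for a translational analyst is not whether the data are
normal (they are not) but **how much the shape of the distribution changes
the answers**: the genes called differentially expressed, the annotation
terms flagged as enriched, and the class assigned to a new tumor.

`exprdist` is built for that question. It provides:

* **Central-moments diagnostics** — pooled and per-gene mean, variance,
  skewness g₁ = m₃/m₂^{3/2} and excess kurtosis g₂ = m₄/m₂² − 3, with
  Fisher's indices g₁/√(6/n) and g₂/√(24/n) (significant beyond ±1.96),
  t/Wilcoxon/χ²-variance tests against a simulated standard normal, and
  one/two-sample Kolmogorov–Smirnov tests with critical value
  c(α)/√n, c(0.05) = 1.3581.
* **Empiric curve fitting** — Freedman–Diaconis binning (2·IQR·n^{−1/3}),
  maximum-likelihood fits of eight candidate families (normal, logistic,
  Laplace, hyperbolic secant, log-logistic 3P, Dagum 4P, Burr XII 4P,
  Johnson SU), KS-ranked best-fit lists with PP/QQ tie-breaks, and a
  plugin registry for further families.
* **Box-Cox normalization** — ((x+c)^λ − 1)/λ with profile-likelihood λ
  selection, shift handling for signed log ratios, recentering, and a
  before/after moments report.
* **Four gene callers implemented from their defining procedures** —
  Bonferroni-corrected pooled t (p < 0.01), two-class unpaired SAM
  (d = Δmean/(s + s₀), permutation null, median-FDR Δ selection, FDR = 0
  default), Kruskal–Wallis + Benjamini–Hochberg (FDR < 0.05), and an
  empirical-Bayes moderated t with closed-form (d₀, s₀²) estimation.
* **Hypergeometric term enrichment** on GMT annotation tables
  (Bonferroni p < 0.01).
* **Prospective classification** — ANOVA → PLS → linear-discriminant
  pipeline and a 2-class, 4-neighbor KNN, with a seeded 8 + 5 / 7 + 3
  train/test protocol and t-test or SAM gene pre-filtering.
* **Sensitivity reports** — run any caller/classifier identically on the
  parent and Box-Cox-transformed matrix and report overlap
  (pct_unique = 100·|unique|/|union|, the distribution-dependent
  variability) and classification discordance.
* **A synthetic-data module** that generates every input above with
  controlled shape (Gaussian or Johnson SU noise, planted effects,
  reference profiles, planted annotation terms), so the whole pipeline is
  testable offline.

## Worked example

```r
library(exprdist)

# A 2,000-gene, 15 + 8-sample two-class set over skewed Johnson SU noise,
# with 100 genes shifted by 1.5 log2 units
design <- two_class_design(2000, 15, 8, n_de = 100, effect_size = 1.5,
                           noise = skewed_noise_spec(), seed = 20260922)
em <- gen_two_class(design)

# Is the pooled distribution normal?
print(central_moments(as.numeric(em$values)))
#> Central moments (n = 46000)
#>   mean 0.4901  variance 0.7307  sd 0.8548
#>   skewness 0.9275 (Fisher index 81.21)
#>   excess kurtosis 3.4229 (Fisher index 149.9)

# How does the distribution shape change gene calling?
sens <- run_sensitivity(em, caller = "ttest_bonferroni",
                        caller_args = list(alpha = 0.01),
                        classifier = "knn",
                        classifier_args = list(prefilter_args = list(alpha = 0.05)),
                        seed = 1)
print(sens)
#> sensitivity (ttest_bonferroni, transform = boxcox): 15 vs 13 genes called
#> overlap: |A| = 15, |B| = 13, common 12 (75.0%), unique 4 (25.0%)
#> classification discordance: 2/10 (20.0%)
```

The numbers mean: the Bonferroni t-test called 15 genes on the parent
matrix and 13 after a pure shape change (Box-Cox λ fitted by profile
likelihood, then recentering) — 25% of the union appears in only one of
the two lists — and the 4-neighbor KNN classifier assigned a different
class to 2 of the 10 held-out tumors. Running the same report with
`caller = "kruskal_wallis_bh"` gives 100% overlap: rank statistics are
exactly invariant under the monotone transform.

## The analysis workflow

Numbered drivers under `analysis/` rebuild the full study on synthetic
data and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates the pooled (2,000 × 180) skewed/Gaussian matrices, the 15 + 8 two-class set, reference profiles, annotation GMT |
| `02_moments.R` | pooled normality reports and per-gene moment tables |
| `03_distfit.R` | FD histogram, 8-family MLE fits, KS ranking, PP/QQ data |
| `04_boxcox.R` | Box-Cox transform with before/after moments |
| `05_gene_calling.R` | all four callers, parent vs transformed, overlap table |
| `06_enrichment.R` | term enrichment of SAM/KW lists, term-set overlap |
| `07_classification.R` | DA and KNN discordance, plus a 20-seed KNN sweep |

Run them in order with `Rscript analysis/01_simulate.R` etc.

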