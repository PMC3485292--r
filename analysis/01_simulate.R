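#!/usr/bin/env Rscript
# Generate every input the downstream stages need: a pooled "cancer-like"
# matrix with Johnson SU (skewed, heavy-tailed) noise, an all-Gaussian
# control matrix, a two-class tumor set in the 15 + 8 low-grade-glioma
# configuration, replicate normal-reference profiles, and an annotation
# table with the differentially-expressed block planted as a term.

suppressPackageStartupMessages(library(exprdist))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
seed <- 20260920L

# Pooled matrices: 2,000 genes x 180 samples (a scaled-down version of the
# 180-sample pooled sets), skewed and Gaussian variants.
skewed <- gen_matrix(skewed_noise_spec(2000), 180, seed = seed)
gaussian <- gen_matrix(dist_spec("normal", c(0, 1), 2000), 180, seed = seed + 1)
write_expr_tsv(skewed, "results/data/pooled_skewed.tsv")
write_expr_tsv(gaussian, "results/data/pooled_gaussian.tsv")

# Two-class tumor set: 15 vs 8 samples, 2,000 genes, 100 shifted genes at
# a moderate 1.5 log2-unit effect over the skewed noise.
design <- two_class_design(2000, 15, 8, n_de = 100, effect_size = 1.5,
                           noise = skewed_noise_spec(), seed = seed + 2)
tumors <- gen_two_class(design)
write_expr_tsv(tumors, "results/data/two_class.tsv")
write_labels_tsv(tumors, "results/data/two_class_labels.tsv")

# Three replicate normal-tissue profiles on the linear scale, plus the
# log2 reference and the log2-subtracted tumor matrix built from a
# linear-scale rendition of the tumor data.
profiles <- gen_reference_profiles(2000, 3, seed = seed + 3)
ref <- build_reference(profiles)
lin_tumors <- expression_matrix(2^(tumors$values + log2(rowMeans(profiles))),
                                labels = tumors$labels)
ratios <- log_subtract(log2_transform(lin_tumors), ref)
write_expr_tsv(ratios, "results/data/two_class_log2_subtracted.tsv")

# Annotation: 40 random terms plus the planted DE term.
ann <- gen_annotation(2000, 40, term_sizes = c(15, 25, 40),
                      planted = list(DE_BLOCK = rownames(tumors$values)[1:100]),
                      seed = seed + 4, gene_ids = rownames(tumors$values))
write_gmt(ann, "results/data/annotation.gmt")

cat("Simulated inputs written to results/data/:\n")
cat(sprintf("  pooled skewed/gaussian: 2000 x 180 (pooled skewness %.2f vs %.2f)\n",
            sample_skewness(as.numeric(skewed$values)),
            sample_skewness(as.numeric(gaussian$values))))
cat(sprintf("  two-class set: %d x %d, 100 planted genes, effect 1.5 log2 units\n",
            nrow(tumors$values), ncol(tumors$values)))
cat(sprintf("  reference: %d genes x 3 profiles; annotation: %d terms\n",
            nrow(profiles), length(ann$terms)))
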