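#!/usr/bin/env Rscript
# Gene calling on parent vs Box-Cox-transformed data with all four
# callers, plus the overlap table (the distribution-dependent variability
# of each method).

suppressPackageStartupMessages(library(exprdist))
dir.create("results", showWarnings = FALSE)
seed <- 11L

em <- read_expr_tsv("results/data/two_class.tsv",
                    labels_path = "results/data/two_class_labels.tsv")

callers <- list(
  sam = list(caller = "sam",
             args = list(target_fdr = 0, n_perm = 500)),
  kruskal_wallis = list(caller = "kruskal_wallis_bh", args = list(fdr = 0.05)),
  ttest = list(caller = "ttest_bonferroni", args = list(alpha = 0.01)),
  moderated_t = list(caller = "moderated_t", args = list(alpha = 0.05))
)

rows <- list()
for (name in names(callers)) {
  cfg <- callers[[name]]
  sens <- run_sensitivity(em, caller = cfg$caller, caller_args = cfg$args,
                          classifier = NULL, seed = seed)
  ov <- sens$gene_overlap
  rows[[name]] <- data.frame(
    method = name,
    parent = ov$size_a, transformed = ov$size_b,
    union = ov$union, common = ov$intersection,
    unique_to_one = ov$unique_to_one,
    pct_unique = ov$pct_unique, pct_common = ov$pct_common,
    pct_size_difference = sens$pct_size_difference)
  for (side in c("parent", "transformed")) {
    res <- sens$calls[[side]]
    df <- data.frame(gene_id = res$called,
                     statistic = res$statistic[res$called])
    if (!is.null(res$p_raw)) df$p_raw <- res$p_raw[res$called]
    write_plot_tsv(df, sprintf("results/calls_%s_%s.tsv", name, side))
  }
  write_report_json(sens, sprintf("results/sensitivity_%s.json", name))
}

tab <- do.call(rbind, rows)
write_plot_tsv(tab, "results/gene_calling_overlap.tsv")
print(tab, row.names = FALSE)

cat("\nThe rank-based Kruskal-Wallis caller is exactly invariant under the\n")
cat("monotone Box-Cox transform (100% overlap); the parametric t and\n")
cat("moderated-t callers, and SAM, shift their call sets with the\n")
cat("distribution shape.\n")
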