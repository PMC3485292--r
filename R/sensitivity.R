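# Distribution-sensitivity statistics: overlap between gene (or term)
# lists from parent vs transformed data, and discordance between
# classification outputs.

#' Overlap statistics for two id lists
#'
#' Exact set arithmetic on two gene- or term-id sets: sizes, intersection,
#' union, genes unique to one list, and the percentages
#' pct_unique = 100 * unique/union (the distribution-dependent variability
#' statistic) and pct_common = 100 * intersection/union. Percentages are
#' reported to one decimal; the raw fractions are kept alongside.
#'
#' @param list_a,list_b Character vectors (empty allowed).
#' @return An `overlap_report`: `size_a`, `size_b`, `intersection`,
#'   `union`, `unique_to_one`, `pct_unique`, `pct_common`,
#'   `frac_unique`, `frac_common`, and `undefined` (both lists empty).
#' @export
overlap_report <- function(list_a, list_b) {
  a <- unique(as.character(list_a))
  b <- unique(as.character(list_b))
  i <- length(intersect(a, b))
  u <- length(union(a, b))
  uniq <- u - i
  undefined <- u == 0L
  structure(list(size_a = length(a), size_b = length(b),
                 intersection = i, union = u, unique_to_one = uniq,
                 frac_unique = if (undefined) NA_real_ else uniq / u,
                 frac_common = if (undefined) NA_real_ else i / u,
                 pct_unique = if (undefined) NA_real_ else pct1(uniq / u),
                 pct_common = if (undefined) NA_real_ else pct1(i / u),
                 undefined = undefined),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap: |A| = %d, |B| = %d, common %d (%.1f%%), unique %d (%.1f%%)\n",
              x$size_a, x$size_b, x$intersection, x$pct_common,
              x$unique_to_one, x$pct_unique))
  invisible(x)
}

#' Percent difference in list sizes
#'
#' The alternate "percent difference" phrasing used alongside the overlap
#' statistic: 100 * |size_a - size_b| / max(size_a, size_b). Labeled
#' distinctly from `pct_unique`, which is the variability statistic proper.
#'
#' @param size_a,size_b List sizes.
#' @return Percentage to one decimal.
#' @export
pct_size_difference <- function(size_a, size_b) {
  if (max(size_a, size_b) == 0) return(NA_real_)
  pct1(abs(size_a - size_b) / max(size_a, size_b))
}

#' Discordance between two predicted label vectors
#'
#' @param pred_a,pred_b Equal-length label vectors in the same sample
#'   order.
#' @return List with `count` and `percent` (= 100 count / n, one decimal).
#' @export
discordance <- function(pred_a, pred_b) {
  if (length(pred_a) != length(pred_b))
    stop("discordance: prediction vectors differ in length")
  n <- length(pred_a)
  cnt <- sum(as.character(pred_a) != as.character(pred_b))
  list(count = cnt, percent = pct1(cnt / n))
}

#' Parent-versus-transformed sensitivity analysis
#'
#' Runs an identical procedure on the parent matrix and its Box-Cox
#' transform and reports how the distribution shape changed the outcome:
#' paired gene-call results with their overlap, optionally paired
#' enrichment results with term overlap, and paired train/test
#' classification with the discordance between the two test predictions.
#' Fully deterministic for a fixed seed.
#'
#' @param x Labeled `expr_matrix` (or matrix plus `labels`).
#' @param labels Two-class labels.
#' @param caller Gene-caller id (see [call_genes()]).
#' @param caller_args List of extra arguments for the caller.
#' @param classifier `"knn"`, `"da"` or `NULL` to skip classification.
#' @param classifier_args List: for knn `k`, `scale`; for da
#'   `n_components`, `anova_alpha`; plus `n_train_c1`, `n_train_c2`,
#'   `prefilter` (method for [prefilter_genes()]) and `prefilter_args`.
#' @param transform `"boxcox"` (default) or `"identity"` (control).
#' @param annotation Optional [annotation_table()] for term enrichment of
#'   the called lists.
#' @param enrich_alpha Bonferroni threshold for [enrich()].
#' @param seed Integer seed driving the SAM permutations and the
#'   train/test split.
#' @return A `sensitivity_report` list; see the fields in the example
#'   report written by [write_sensitivity_json()].
#' @export
run_sensitivity <- function(x, labels = NULL, caller = "ttest_bonferroni",
                            caller_args = list(),
                            classifier = "knn", classifier_args = list(),
                            transform = c("boxcox", "identity"),
                            annotation = NULL, enrich_alpha = 0.01,
                            seed = 1L) {
  transform <- match.arg(transform)
  m <- em_values(x)
  labels <- em_labels(x, labels)
  parent <- expression_matrix(m, labels = labels)

  bc <- NULL
  transformed <- if (transform == "boxcox") {
    bc <- transform_for_normality(parent)
    bc$transformed
  } else parent

  seeded <- function(args) {
    if (identical(caller, "sam") && is.null(args$seed)) args$seed <- seed
    args
  }
  call_parent <- do.call(call_genes,
                         c(list(method = caller, x = parent),
                           seeded(caller_args)))
  call_trans <- do.call(call_genes,
                        c(list(method = caller, x = transformed),
                          seeded(caller_args)))
  gene_overlap <- overlap_report(call_parent$called, call_trans$called)

  enr <- NULL
  if (!is.null(annotation)) {
    e_parent <- enrich(call_parent$called, annotation, alpha = enrich_alpha)
    e_trans <- enrich(call_trans$called, annotation, alpha = enrich_alpha)
    enr <- list(parent = e_parent, transformed = e_trans,
                term_overlap = compare_enrichment(e_parent, e_trans))
  }

  cls <- NULL
  if (!is.null(classifier)) {
    ca <- classifier_args
    split <- split_train_test(stats::setNames(labels, colnames(m)),
                              n_train_c1 = ca[["n_train_c1"]] %||% 8L,
                              n_train_c2 = ca[["n_train_c2"]] %||% 5L,
                              seed = seed)
    classify_on <- function(em) {
      v <- em_values(em)
      tr <- v[, split$train, drop = FALSE]
      te <- v[, split$test, drop = FALSE]
      tr_lab <- labels[match(split$train, colnames(m))]
      te_lab <- labels[match(split$test, colnames(m))]
      pf_args <- ca[["prefilter_args"]] %||% list()
      if (identical(ca[["prefilter"]] %||% "bonferroni_t", "sam") &&
          is.null(pf_args$seed)) pf_args$seed <- seed
      genes <- do.call(prefilter_genes,
                       c(list(x = tr, labels = tr_lab,
                              method = ca[["prefilter"]] %||% "bonferroni_t"),
                         pf_args))
      tr <- tr[genes, , drop = FALSE]
      te <- te[genes, , drop = FALSE]
      if (identical(classifier, "knn")) {
        knn_classify(tr, tr_lab, te, k = ca[["k"]] %||% 4L,
                     scale = ca[["scale"]] %||% TRUE, reference = te_lab)
      } else {
        model <- train_da(tr, tr_lab,
                          n_components = ca[["n_components"]] %||% 3L,
                          anova_alpha = ca[["anova_alpha"]] %||% 0.01)
        predict_da(model, te, reference = te_lab)
      }
    }
    pred_parent <- classify_on(parent)
    pred_trans <- classify_on(transformed)
    cls <- list(parent = pred_parent, transformed = pred_trans,
                split = split,
                discordance = discordance(pred_parent$predicted,
                                          pred_trans$predicted))
  }

  structure(list(
    caller = caller, classifier = classifier, transform = transform,
    seed = seed,
    boxcox = if (!is.null(bc)) list(lambda = bc$lambda, shift = bc$shift),
    calls = list(parent = call_parent, transformed = call_trans),
    gene_overlap = gene_overlap,
    pct_size_difference = pct_size_difference(length(call_parent$called),
                                              length(call_trans$called)),
    enrichment = enr,
    classification = cls
  ), class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("sensitivity (%s, transform = %s): %d vs %d genes called\n",
              x$caller, x$transform, length(x$calls$parent$called),
              length(x$calls$transformed$called)))
  print(x$gene_overlap)
  if (!is.null(x$enrichment)) {
    cat("term lists: ")
    print(x$enrichment$term_overlap)
  }
  if (!is.null(x$classification))
    cat(sprintf("classification discordance: %d/%d (%.1f%%)\n",
                x$classification$discordance$count,
                length(x$classification$parent$predicted),
                x$classification$discordance$percent))
  invisible(x)
}
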