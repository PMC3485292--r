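# Synthetic-data generators: expression matrices with controlled
# distributional shape, two-class designs, reference profiles and
# annotation tables. These emulate the study conditions of the real
# datasets (180-sample pooled cancer sets; a ~23-sample two-class
# low-grade-glioma set) so every downstream stage is testable without
# external downloads.

#' Construct an expression matrix container
#'
#' A light container for a genes x samples matrix of log2-scale values with
#' gene/sample ids and optional two-class sample labels.
#'
#' @param values Numeric matrix, genes in rows.
#' @param gene_ids Character vector, one per row (default from rownames).
#' @param sample_ids Character vector, one per column.
#' @param labels Optional class label per sample.
#' @return An `expr_matrix` object (list with `values`, `labels`).
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values), labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(ncol(values)))
  if (length(gene_ids) != nrow(values) || anyDuplicated(gene_ids))
    stop("gene_ids must be unique and match the row count")
  if (length(sample_ids) != ncol(values) || anyDuplicated(sample_ids))
    stop("sample_ids must be unique and match the column count")
  dimnames(values) <- list(gene_ids, sample_ids)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != ncol(values))
      stop("labels must have one entry per sample")
    if (any(table(labels) < 1)) stop("every class needs at least one sample")
  }
  structure(list(values = values, labels = labels), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels: ", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Specify one block of genes drawn from a distribution family
#'
#' @param family Family id (see [list_families()]).
#' @param params Named or positional parameter vector for the family.
#' @param n_genes Number of genes in the block.
#' @return A `dist_spec` object.
#' @export
dist_spec <- function(family, params, n_genes = 1L) {
  fam <- get_family(family)
  params <- check_params(fam, params)
  n_genes <- as.integer(n_genes)
  if (n_genes < 1L) stop("n_genes must be >= 1")
  structure(list(family = fam$name, params = params, n_genes = n_genes),
            class = "dist_spec")
}

#' Generate an expression matrix from distribution blocks
#'
#' Every value of a block's genes is drawn i.i.d. from that block's family;
#' deterministic for a fixed seed.
#'
#' @param specs A `dist_spec` or list of them.
#' @param n_samples Number of samples (columns), >= 2.
#' @param seed Integer seed.
#' @return An `expr_matrix` (no labels).
#' @export
gen_matrix <- function(specs, n_samples, seed) {
  if (inherits(specs, "dist_spec")) specs <- list(specs)
  if (!length(specs) || !all(vapply(specs, inherits, logical(1), "dist_spec")))
    stop("specs must be dist_spec objects")
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L) stop("n_samples must be >= 2")
  set_call_seed(seed)
  blocks <- lapply(specs, function(sp) {
    fam <- get_family(sp$family)
    matrix(fam$rand(sp$n_genes * n_samples, sp$params),
           nrow = sp$n_genes, ncol = n_samples)
  })
  values <- do.call(rbind, blocks)
  expression_matrix(values,
                    gene_ids = sprintf("g%05d", seq_len(nrow(values))),
                    sample_ids = sprintf("s%03d", seq_len(n_samples)))
}

#' Specify a two-class differential-expression design
#'
#' Emulates a two-subgroup tumor set: `n_de` genes carry a class-2 mean
#' shift of `effect_size` log2 units on top of the noise family; the rest
#' are null. Default class sizes 15 vs 8 mirror the two-subgroup glioma
#' design implied by the 8+7 / 5+3 train/test split; an 11 vs 8 variant is
#' equally expressible.
#'
#' @param n_genes Total genes.
#' @param n_class1,n_class2 Samples per class (each >= 2).
#' @param n_de Number of shifted genes, 0 <= n_de <= n_genes.
#' @param effect_size Class-2 mean shift in log2 units.
#' @param noise A `dist_spec` giving the per-gene noise family (its
#'   `n_genes` field is ignored); default standard normal.
#' @param seed Integer seed.
#' @return A `two_class_design` object.
#' @export
two_class_design <- function(n_genes, n_class1 = 15L, n_class2 = 8L,
                             n_de = 0L, effect_size = 0,
                             noise = dist_spec("normal", c(0, 1)), seed = 1L) {
  n_genes <- as.integer(n_genes); n_de <- as.integer(n_de)
  if (n_de < 0L || n_de > n_genes)
    stop("design error: n_de must satisfy 0 <= n_de <= n_genes")
  if (n_class1 < 2L || n_class2 < 2L) stop("each class needs >= 2 samples")
  if (!inherits(noise, "dist_spec")) stop("noise must be a dist_spec")
  structure(list(n_genes = n_genes, n_class1 = as.integer(n_class1),
                 n_class2 = as.integer(n_class2), n_de = n_de,
                 effect_size = effect_size, noise = noise,
                 seed = as.integer(seed)),
            class = "two_class_design")
}

#' Generate a labeled two-class expression matrix
#'
#' @param design A [two_class_design()].
#' @return An `expr_matrix` with labels `"Class1"` / `"Class2"`; the first
#'   `n_de` genes have their class-2 mean shifted by `effect_size`.
#' @export
gen_two_class <- function(design) {
  stopifnot(inherits(design, "two_class_design"))
  n <- design$n_class1 + design$n_class2
  noise <- design$noise
  noise$n_genes <- design$n_genes
  em <- gen_matrix(list(noise), n_samples = n, seed = design$seed)
  if (design$n_de > 0L && design$effect_size != 0) {
    cls2 <- design$n_class1 + seq_len(design$n_class2)
    em$values[seq_len(design$n_de), cls2] <-
      em$values[seq_len(design$n_de), cls2] + design$effect_size
  }
  em$labels <- c(rep("Class1", design$n_class1), rep("Class2", design$n_class2))
  em
}

#' Generate linear-scale reference expression profiles
#'
#' Strictly positive intensities (log-normal by default) for building an
#' averaged normal-tissue reference; at least three replicate profiles by
#' default.
#'
#' @param n_genes Number of genes.
#' @param n_profiles Number of replicate profiles (default and conventional
#'   minimum 3).
#' @param seed Integer seed.
#' @param meanlog,sdlog Log-normal intensity parameters (log2 intensities
#'   around `meanlog/log(2)`).
#' @param identical_profiles If TRUE all columns are identical (useful for
#'   exact checks).
#' @return Numeric matrix genes x profiles, all values > 0.
#' @export
gen_reference_profiles <- function(n_genes, n_profiles = 3L, seed,
                                   meanlog = log(2) * 7, sdlog = 0.5,
                                   identical_profiles = FALSE) {
  n_genes <- as.integer(n_genes); n_profiles <- as.integer(n_profiles)
  if (n_profiles < 1L) stop("n_profiles must be >= 1")
  set_call_seed(seed)
  if (identical_profiles) {
    base <- stats::rlnorm(n_genes, meanlog, sdlog)
    m <- matrix(rep(base, n_profiles), ncol = n_profiles)
  } else {
    m <- matrix(stats::rlnorm(n_genes * n_profiles, meanlog, sdlog),
                nrow = n_genes, ncol = n_profiles)
  }
  dimnames(m) <- list(sprintf("g%05d", seq_len(n_genes)),
                      sprintf("ref%02d", seq_len(n_profiles)))
  m
}

#' Generate a gene -> term annotation table
#'
#' Random term memberships plus optional planted terms mapped to designated
#' gene subsets (e.g. the differentially-expressed block of a two-class
#' design), GMT-serializable.
#'
#' @param n_genes Background size; genes are `g00001 ...` as in
#'   [gen_matrix()], or pass `gene_ids`.
#' @param n_terms Number of random terms (0 allowed).
#' @param term_sizes Integer vector (recycled) of term sizes, each <=
#'   `n_genes`.
#' @param planted Named list: term name -> character vector of member gene
#'   ids.
#' @param seed Integer seed.
#' @param gene_ids Optional explicit background gene ids.
#' @return An `annotation_table`: list with `terms` (term -> gene-id set)
#'   and `background`.
#' @export
gen_annotation <- function(n_genes, n_terms, term_sizes = 20L,
                           planted = list(), seed = 1L, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(n_genes))
  n_terms <- as.integer(n_terms)
  if (any(term_sizes > length(gene_ids)))
    stop("term sizes must not exceed the number of genes")
  set_call_seed(seed)
  terms <- list()
  if (n_terms > 0L) {
    sizes <- rep_len(as.integer(term_sizes), n_terms)
    terms <- lapply(seq_len(n_terms), function(i) sample(gene_ids, sizes[i]))
    names(terms) <- sprintf("TERM%04d", seq_len(n_terms))
  }
  if (length(planted) > 0L) {
    if (is.null(names(planted)) || any(names(planted) == ""))
      stop("planted terms must be named")
    bad <- unlist(lapply(planted, setdiff, y = gene_ids))
    if (length(bad) > 0)
      stop("planted term genes absent from background: ",
           paste(utils::head(bad, 5), collapse = ", "))
    terms <- c(terms, lapply(planted, as.character))
  }
  if (anyDuplicated(names(terms)))
    stop("duplicate term names: ",
         paste(unique(names(terms)[duplicated(names(terms))]), collapse = ", "))
  annotation_table(terms, background = gene_ids)
}

#' Default skewed noise specification
#'
#' Johnson SU noise with (gamma, delta, xi, lambda) = (-0.6, 1.6, 0, 1):
#' skewness 0.98, excess kurtosis 4.5, variance 0.70 — the pooled-moment
#' regime typical of log2-ratio cancer expression matrices, used as the
#' package's canonical non-Gaussian study condition.
#'
#' @param n_genes Block size.
#' @return A `dist_spec`.
#' @export
skewed_noise_spec <- function(n_genes = 1L) {
  dist_spec("johnson_su", c(gamma = -0.6, delta = 1.6, xi = 0, lambda = 1),
            n_genes = n_genes)
}
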