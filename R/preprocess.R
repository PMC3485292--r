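# Preprocessing: turn normalized linear-scale intensities into the
# log2-ratio ("log2-subtracted") form analyzed throughout the package.

#' Log2-transform a linear-scale matrix
#'
#' @param x Numeric matrix or `expr_matrix` of strictly positive values.
#' @return Same shape, elementwise log2.
#' @export
log2_transform <- function(x) {
  m <- em_values(x)
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    g <- rownames(m)[bad[1, 1]] %||% bad[1, 1]
    s <- colnames(m)[bad[1, 2]] %||% bad[1, 2]
    stop("log2_transform: non-positive value at gene ", g, ", sample ", s,
         " (", nrow(bad), " offending value(s) in total)")
  }
  out <- log2(m)
  if (inherits(x, "expr_matrix")) expression_matrix(out, labels = x$labels) else out
}

#' Build a log2 reference profile from replicate linear-scale profiles
#'
#' Per-gene arithmetic mean on the linear scale, then log2 — average first,
#' convert second. The reverse order (log2 of each profile, then average) is
#' available for sensitivity checks via `order = "log_then_average"`.
#'
#' @param profiles Numeric matrix, genes x replicate profiles, positive.
#' @param min_profiles Minimum replicate count (default 3).
#' @param order Averaging order; default is average-then-log2.
#' @return A `reference_profile`: list with `gene_ids` and `log2_values`.
#' @export
build_reference <- function(profiles, min_profiles = 3L,
                            order = c("average_then_log", "log_then_average")) {
  order <- match.arg(order)
  if (!is.matrix(profiles) || !is.numeric(profiles))
    stop("profiles must be a numeric matrix")
  if (ncol(profiles) < min_profiles)
    stop("build_reference: need at least ", min_profiles,
         " profiles, got ", ncol(profiles))
  if (any(profiles <= 0)) stop("build_reference: profiles must be positive")
  v <- if (order == "average_then_log") log2(rowMeans(profiles))
       else rowMeans(log2(profiles))
  structure(list(gene_ids = rownames(profiles) %||%
                   sprintf("g%05d", seq_len(nrow(profiles))),
                 log2_values = unname(v), order = order),
            class = "reference_profile")
}

#' Align a matrix to a reference gene order by id
#'
#' Explicit alignment step: reorders rows to match `gene_ids` and fails
#' loudly on any mismatch (silent positional matching is a classic
#' microarray bug).
#'
#' @param x Matrix or `expr_matrix` with rownames.
#' @param gene_ids Target gene-id order.
#' @return Input with rows reordered.
#' @export
align_genes <- function(x, gene_ids) {
  m <- em_values(x)
  if (is.null(rownames(m))) stop("align_genes: matrix has no gene ids")
  if (!setequal(rownames(m), gene_ids))
    stop("align_genes: gene sets differ (",
         length(setdiff(gene_ids, rownames(m))), " missing, ",
         length(setdiff(rownames(m), gene_ids)), " extra)")
  out <- m[match(gene_ids, rownames(m)), , drop = FALSE]
  if (inherits(x, "expr_matrix")) expression_matrix(out, labels = x$labels) else out
}

#' Subtract a log2 reference profile from a log2 matrix
#'
#' Produces the log2-subtracted (log2-ratio) matrix. Gene ids must match
#' the reference exactly and in order; use [align_genes()] first if the
#' order differs.
#'
#' @param tumor_log2 Log2-scale matrix or `expr_matrix`.
#' @param reference A [build_reference()] result.
#' @return Matrix (or `expr_matrix`) of log2 ratios.
#' @export
log_subtract <- function(tumor_log2, reference) {
  stopifnot(inherits(reference, "reference_profile"))
  m <- em_values(tumor_log2)
  ids <- rownames(m) %||% stop("log_subtract: matrix has no gene ids")
  if (!identical(ids, reference$gene_ids))
    stop("log_subtract: gene ids do not match the reference",
         if (setequal(ids, reference$gene_ids))
           " (same set, different order; run align_genes first)" else "")
  out <- m - reference$log2_values
  if (inherits(tumor_log2, "expr_matrix"))
    expression_matrix(out, labels = tumor_log2$labels) else out
}

#' Recenter a matrix to zero grand mean
#'
#' Subtracts the grand mean (compensating, e.g., for the default mean of
#' RMA output); idempotent and moment-preserving for variance, skewness and
#' kurtosis.
#'
#' @param x Matrix or `expr_matrix`.
#' @return Same shape with grand mean 0.
#' @export
recenter <- function(x) {
  m <- em_values(x)
  if (any(!is.finite(m))) stop("recenter: non-finite values")
  out <- m - mean(m)
  if (inherits(x, "expr_matrix")) expression_matrix(out, labels = x$labels) else out
}
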