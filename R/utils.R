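# Small shared helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Every stochastic entry point takes an explicit seed; refusing a missing
# seed keeps runs reproducible by construction.
set_call_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed) || !is.finite(seed))
    stop("an explicit integer seed is required")
  set.seed(as.integer(seed))
  invisible(as.integer(seed))
}

# Accept either a bare numeric matrix or an expr_matrix; always return the
# numeric matrix with gene ids as rownames and sample ids as colnames.
em_values <- function(x) {
  if (inherits(x, "expr_matrix")) return(x$values)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expected a numeric matrix or an expr_matrix")
  x
}

# Class labels for a matrix-like input: explicit argument wins, else the
# labels attached to an expr_matrix.
em_labels <- function(x, labels = NULL) {
  if (!is.null(labels)) return(as.character(labels))
  if (inherits(x, "expr_matrix") && !is.null(x$labels))
    return(as.character(x$labels))
  stop("class labels are required (attach them to the expr_matrix or pass `labels`)")
}

check_two_classes <- function(labels, min_per_class = 2L) {
  tab <- table(labels)
  if (length(tab) != 2L)
    stop("exactly two classes required, got ", length(tab), ": ",
         paste(names(tab), collapse = ", "))
  if (any(tab < min_per_class))
    stop("each class needs at least ", min_per_class, " samples")
  names(tab)
}

# Round a fraction to a percentage with one decimal, as reported in the
# overlap tables; the raw fraction is kept alongside wherever this is used.
pct1 <- function(x) round(100 * x, 1)
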