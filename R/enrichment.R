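# Term over-representation analysis of called gene lists against a
# user-supplied (or synthetic) annotation table, with Bonferroni control.

#' Construct an annotation table
#'
#' @param terms Named list: term name -> character vector of member gene
#'   ids; every annotated gene must be in the background, terms non-empty.
#' @param background Character vector of all assayable gene ids.
#' @return An `annotation_table`.
#' @export
annotation_table <- function(terms, background) {
  background <- unique(as.character(background))
  if (length(terms)) {
    if (is.null(names(terms)) || any(names(terms) == ""))
      stop("terms must be named")
    if (anyDuplicated(names(terms)))
      stop("duplicate term names: ",
           paste(unique(names(terms)[duplicated(names(terms))]), collapse = ", "))
    terms <- lapply(terms, function(g) unique(as.character(g)))
    if (any(lengths(terms) == 0)) stop("terms must be non-empty")
    outside <- setdiff(unique(unlist(terms)), background)
    if (length(outside))
      stop("annotated genes absent from the background: ",
           paste(utils::head(outside, 5), collapse = ", "))
  }
  structure(list(terms = terms, background = background),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("annotation_table: %d terms over %d background genes\n",
              length(x$terms), length(x$background)))
  invisible(x)
}

#' Term over-representation of a called gene list
#'
#' One-sided hypergeometric upper-tail (Fisher) test per term of whether
#' the called list hits the term more often than expected from the
#' background; Bonferroni correction over the tested terms, called terms at
#' Bonferroni p < `alpha`. The EASE variant (hits decremented by one, as in
#' the DAVID score) is available via `ease = TRUE`.
#'
#' @param called Character vector of called gene ids, a subset of the
#'   background.
#' @param annotation An [annotation_table()].
#' @param alpha Bonferroni-corrected significance threshold (default 0.01).
#' @param ease Apply the EASE one-hit penalty.
#' @return An `enrichment_result`: data frame `table` (term, hits,
#'   list_size, term_size, background_size, p_raw, p_bonferroni) plus
#'   `called_terms` and the parameters.
#' @export
enrich <- function(called, annotation, alpha = 0.01, ease = FALSE) {
  stopifnot(inherits(annotation, "annotation_table"))
  called <- unique(as.character(called))
  offenders <- setdiff(called, annotation$background)
  if (length(offenders))
    stop("called genes absent from the annotation background: ",
         paste(utils::head(offenders, 5), collapse = ", "))
  N <- length(annotation$background)
  k <- length(called)
  n_terms <- length(annotation$terms)
  if (n_terms == 0L) {
    tab <- data.frame(term = character(0), hits = integer(0),
                      list_size = integer(0), term_size = integer(0),
                      background_size = integer(0), p_raw = numeric(0),
                      p_bonferroni = numeric(0))
    return(structure(list(table = tab, called_terms = character(0),
                          alpha = alpha, ease = ease,
                          annotation_signature = annotation_signature(annotation)),
                     class = "enrichment_result"))
  }
  hits <- vapply(annotation$terms, function(g) length(intersect(g, called)),
                 integer(1))
  sizes <- lengths(annotation$terms)
  q <- if (ease) pmax(hits - 1L, 0L) else hits
  # upper tail P(X >= q) for X ~ Hypergeometric(term, N - term, list)
  p <- stats::phyper(q - 1L, sizes, N - sizes, k, lower.tail = FALSE)
  p_bonf <- pmin(p * n_terms, 1)
  tab <- data.frame(term = names(annotation$terms), hits = hits,
                    list_size = k, term_size = sizes, background_size = N,
                    p_raw = p, p_bonferroni = p_bonf, row.names = NULL)
  tab <- tab[order(tab$p_raw, tab$term), ]
  structure(list(table = tab,
                 called_terms = tab$term[tab$p_bonferroni < alpha],
                 alpha = alpha, ease = ease,
                 annotation_signature = annotation_signature(annotation)),
            class = "enrichment_result")
}

annotation_signature <- function(annotation) {
  list(n_terms = length(annotation$terms),
       term_names = sort(names(annotation$terms)),
       n_background = length(annotation$background))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: %d of %d terms called at Bonferroni p < %g\n",
              length(x$called_terms), nrow(x$table), x$alpha))
  print(utils::head(x$table, 10), row.names = FALSE)
  invisible(x)
}

#' Compare enriched-term sets between parent and transformed runs
#'
#' Overlap statistics on the called term sets of two enrichment results
#' computed against the same annotation.
#'
#' @param parent,transformed `enrichment_result`s from [enrich()].
#' @return An `overlap_report` (see [overlap_report()]).
#' @export
compare_enrichment <- function(parent, transformed) {
  stopifnot(inherits(parent, "enrichment_result"),
            inherits(transformed, "enrichment_result"))
  if (!identical(parent$annotation_signature, transformed$annotation_signature))
    stop("compare_enrichment: results were computed against different annotations")
  overlap_report(parent$called_terms, transformed$called_terms)
}
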