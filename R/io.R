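# File formats: expression TSV (first column gene_id, header = sample
# ids), two-column label TSV, GMT annotation tables, JSON reports, and
# TSV plot data. NA is forbidden in analysis inputs; parse errors name the
# offending line.

#' Read an expression matrix from TSV
#'
#' Tab-separated, UTF-8, header row of sample ids, first column `gene_id`,
#' no quoting. Ragged rows, missing values and duplicate gene ids are
#' errors naming the line.
#'
#' @param path File path.
#' @param labels_path Optional two-column label TSV (sample_id, class) to
#'   attach.
#' @return An `expr_matrix`.
#' @export
read_expr_tsv <- function(path, labels_path = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2) stop(path, ": expected a header and at least one gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (header[1] != "gene_id")
    stop(path, ": first header column must be 'gene_id', got '", header[1], "'")
  width <- length(header)
  nf <- lengths(fields)
  bad <- which(nf != width)[which(nf != width) > 1][1]
  if (!is.na(bad))
    stop(path, ": ragged row at line ", bad, " (", nf[bad], " fields, expected ",
         width, ")")
  body <- fields[-1]
  gene_ids <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(gene_ids))
    stop(path, ": duplicate gene ids (first: ",
         gene_ids[duplicated(gene_ids)][1], ")")
  values <- matrix(NA_real_, nrow = length(body), ncol = width - 1L)
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (any(is.na(v)))
      stop(path, ": missing or non-numeric value at line ", i + 1L,
           " (gene ", gene_ids[i], "); NA is not allowed in analysis inputs")
    values[i, ] <- v
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- read_labels_tsv(labels_path)
    missing <- setdiff(header[-1], names(lab))
    if (length(missing))
      stop(labels_path, ": no class for sample(s) ",
           paste(utils::head(missing, 5), collapse = ", "))
    labels <- unname(lab[header[-1]])
  }
  expression_matrix(values, gene_ids = gene_ids, sample_ids = header[-1],
                    labels = labels)
}

#' Write an expression matrix as TSV
#'
#' @param x Matrix or `expr_matrix`.
#' @param path Output path.
#' @param digits Significant digits for the numeric text (default 12, so
#'   re-runs are byte-identical).
#' @return `path`, invisibly.
#' @export
write_expr_tsv <- function(x, path, digits = 12) {
  m <- em_values(x)
  ids <- rownames(m) %||% sprintf("g%05d", seq_len(nrow(m)))
  samples <- colnames(m) %||% sprintf("s%03d", seq_len(ncol(m)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", samples), collapse = "\t"), con)
  body <- apply(signif(m, digits), 1, paste, collapse = "\t")
  writeLines(paste(ids, body, sep = "\t"), con)
  invisible(path)
}

#' Read a two-column label TSV (sample_id, class)
#' @param path File path.
#' @return Named character vector, sample id -> class.
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (!all(c("sample_id", "class") %in% names(df)))
    stop(path, ": expected columns 'sample_id' and 'class'")
  if (anyDuplicated(df$sample_id)) stop(path, ": duplicate sample ids")
  stats::setNames(df$class, df$sample_id)
}

#' Write labels as a two-column TSV
#' @param labels Named character vector or `expr_matrix` with labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(labels, path) {
  if (inherits(labels, "expr_matrix")) {
    labels <- stats::setNames(labels$labels %||%
                                stop("expr_matrix carries no labels"),
                              colnames(labels$values))
  }
  utils::write.table(data.frame(sample_id = names(labels),
                                class = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT annotation file
#'
#' Lines of: term, description, tab-separated gene ids.
#'
#' @param path File path.
#' @param background Background gene set; defaults to the union of all
#'   annotated genes.
#' @return An [annotation_table()].
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(path, ": GMT line ", short[1],
         " has fewer than 3 fields (term, description, genes...)")
  terms <- lapply(fields, function(f) f[-(1:2)])
  names(terms) <- vapply(fields, `[[`, character(1), 1)
  annotation_table(terms, background %||% unique(unlist(terms)))
}

#' Write an annotation table as GMT
#'
#' @param annotation An [annotation_table()].
#' @param path Output path.
#' @param description Per-term description (recycled; default "na").
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotation, path, description = "na") {
  stopifnot(inherits(annotation, "annotation_table"))
  desc <- rep_len(description, length(annotation$terms))
  lines <- vapply(seq_along(annotation$terms), function(i) {
    paste(c(names(annotation$terms)[i], desc[i], annotation$terms[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Strip closures/heavy objects down to JSON-friendly values.
json_ready <- function(x) {
  if (is.function(x)) return(NULL)
  if (inherits(x, "expr_matrix")) return(list(n_genes = nrow(x$values),
                                              n_samples = ncol(x$values)))
  if (is.environment(x)) return(NULL)
  if (is.list(x)) {
    out <- lapply(unclass(x), json_ready)
    return(out[!vapply(out, is.null, logical(1))])
  }
  x
}

#' Write any report object as JSON
#'
#' Reports embed their parameters and seed verbatim so a run can be
#' reproduced from its artifact; numbers are written at full precision.
#'
#' @param report A report list (e.g. `sensitivity_report`,
#'   `normality_report`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(json_ready(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
write_sensitivity_json <- write_report_json

#' Write two-column plot data (e.g. QQ/PP series, histograms) as TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plot_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
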