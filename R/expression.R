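#' Tags-per-million normalisation
#'
#' Scales a tag count to a library of one million clean tags:
#' `count / total * 1e6`.
#'
#' @param count Tag count(s).
#' @param total Library total clean tags (> 0).
#' @return Numeric TPM value(s).
#' @export
normalize_tpm <- function(count, total) {
  if (any(!is.finite(total)) || any(total <= 0))
    stopf("library total must be positive")
  if (any(count < 0)) stopf("counts must be non-negative")
  count / total * 1e6
}

#' Reads-per-kilobase-per-million normalisation
#'
#' `count / (length / 1000) / (total / 1e6)`.
#'
#' @param count Read count(s).
#' @param length Gene length(s) in bp (> 0).
#' @param total Library total mapped reads (> 0).
#' @return Numeric RPKM value(s).
#' @export
normalize_rpkm <- function(count, length, total) {
  if (any(!is.finite(length)) || any(length <= 0))
    stopf("gene length must be positive")
  if (any(!is.finite(total)) || any(total <= 0))
    stopf("library total must be positive")
  if (any(count < 0)) stopf("counts must be non-negative")
  count / (length / 1000) / (total / 1e6)
}

#' Assemble a gene-by-library expression matrix
#'
#' Raw counts come from unique matches only.  Per-library totals are the
#' total clean tags of each library (the denominator of tags-per-million),
#' taken from the mapping ledgers when a list of mappings is supplied.
#'
#' @param x Either a named list of `tag_mapping` objects (one per library)
#'   or a gene-by-library count matrix.
#' @param lib_totals Named per-library totals; required when `x` is a
#'   matrix.
#' @param gene_lengths Named gene lengths in bp; required when `x` is a
#'   matrix.
#' @return Object of class `expr_matrix`: list with `counts` (integer
#'   matrix), `lib_totals`, `gene_lengths`.
#' @export
expression_matrix <- function(x, lib_totals = NULL, gene_lengths = NULL) {
  if (is.list(x) && !is.matrix(x) && all(vapply(x, inherits, logical(1),
                                                "tag_mapping"))) {
    counts <- vapply(x, function(m) m$counts,
                     integer(length(x[[1L]]$counts)))
    if (is.null(colnames(counts)) || is.null(names(x)))
      colnames(counts) <- vapply(x, function(m) m$library, character(1))
    if (is.null(lib_totals))
      lib_totals <- vapply(x, function(m) m$ledger[["total_clean"]],
                           numeric(1))
    names(lib_totals) <- colnames(counts)
    if (is.null(gene_lengths)) gene_lengths <- x[[1L]]$gene_lengths
  } else {
    counts <- as.matrix(x)
  }
  if (is.null(lib_totals) || is.null(names(lib_totals)))
    stopf("lib_totals must be a named vector")
  if (is.null(gene_lengths)) stopf("gene_lengths are required")
  if (!all(colnames(counts) %in% names(lib_totals)))
    stopf("lib_totals must name every library column")
  if (any(counts < 0) || any(counts != floor(counts)))
    stopf("counts must be non-negative integers")
  structure(list(counts = counts,
                 lib_totals = lib_totals[colnames(counts)],
                 gene_lengths = gene_lengths[rownames(counts)]),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "libraries\n")
  invisible(x)
}

#' Normalised expression values of an expression matrix
#'
#' @param x An `expr_matrix`.
#' @return Numeric matrix of the same shape.
#' @export
tpm <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  sweep(x$counts, 2, x$lib_totals, function(c, t) normalize_tpm(c, t))
}

#' @rdname tpm
#' @export
rpkm <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  out <- x$counts / (as.numeric(x$gene_lengths) / 1000)
  sweep(out, 2, x$lib_totals / 1e6, `/`)
}
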