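#' Expression matrix container
#'
#' A cells-by-genes numeric matrix with unique cell ids as row names, unique
#' gene names as column names, and an optional per-cell pseudotime stored as
#' an attribute. All analysis functions in the package accept this container
#' (or a plain matrix with dimnames).
#'
#' @param values Numeric matrix, cells in rows, genes in columns. Entries
#'   must be nonnegative.
#' @param cell_ids Character vector of unique cell identifiers (default: row
#'   names of `values`, or `cell_1..cell_n`).
#' @param gene_names Character vector of unique gene names (default: column
#'   names of `values`, or `gene_1..gene_n`).
#' @param pseudotime Optional numeric vector, one value per cell.
#'
#' @return A numeric matrix of class `expr_matrix`.
#' @export
#' @examples
#' m <- expr_matrix(matrix(abs(rnorm(20)), 5, 4))
#' pseudotime(m) <- seq_len(5)
expr_matrix <- function(values, cell_ids = NULL, gene_names = NULL, pseudotime = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (cells x genes).",
          class = "bifurscan_format_error")
  }
  if (any(!is.finite(values))) {
    abort("Expression values must be finite.", class = "bifurscan_format_error")
  }
  if (any(values < 0)) {
    abort("Expression values must be nonnegative.", class = "bifurscan_format_error")
  }
  cell_ids <- cell_ids %||% rownames(values) %||% paste0("cell_", seq_len(nrow(values)))
  gene_names <- gene_names %||% colnames(values) %||% paste0("gene_", seq_len(ncol(values)))
  if (length(cell_ids) != nrow(values)) {
    abort("`cell_ids` length must match the number of rows.",
          class = "bifurscan_format_error")
  }
  if (length(gene_names) != ncol(values)) {
    abort("`gene_names` length must match the number of columns.",
          class = "bifurscan_format_error")
  }
  if (anyDuplicated(cell_ids)) {
    abort("Cell ids must be unique.", class = "bifurscan_format_error")
  }
  if (anyDuplicated(gene_names)) {
    abort("Gene names must be unique.", class = "bifurscan_format_error")
  }
  dimnames(values) <- list(as.character(cell_ids), as.character(gene_names))
  if (!is.null(pseudotime)) {
    if (length(pseudotime) != nrow(values) || !is.numeric(pseudotime)) {
      abort("`pseudotime` must be numeric with one value per cell.",
            class = "bifurscan_format_error")
    }
    attr(values, "pseudotime") <- as.numeric(pseudotime)
  }
  class(values) <- c("expr_matrix", class(values))
  values
}

#' Pseudotime of an expression matrix
#'
#' @param x An `expr_matrix`.
#' @param value Numeric vector, one value per cell, or `NULL` to drop.
#' @return Numeric vector of pseudotimes, or `NULL` when unset.
#' @export
pseudotime <- function(x) attr(x, "pseudotime")

#' @rdname pseudotime
#' @export
`pseudotime<-` <- function(x, value) {
  if (!is.null(value) && (length(value) != nrow(x) || !is.numeric(value))) {
    abort("`pseudotime` must be numeric with one value per cell.",
          class = "bifurscan_format_error")
  }
  attr(x, "pseudotime") <- if (is.null(value)) NULL else as.numeric(value)
  x
}

# Coerce a plain matrix or data frame to the values expected by analysis code.
as_expr_values <- function(x) {
  if (inherits(x, "expr_matrix")) return(unclass_expr(x))
  if (is.data.frame(x)) {
    # tidy input: first column cell id, remaining columns genes
    ids <- as.character(x[[1L]])
    m <- as.matrix(x[, -1L, drop = FALSE])
    rownames(m) <- ids
    storage.mode(m) <- "double"
    return(m)
  }
  if (is.matrix(x) && is.numeric(x)) {
    if (is.null(colnames(x))) colnames(x) <- paste0("gene_", seq_len(ncol(x)))
    if (is.null(rownames(x))) rownames(x) <- paste0("cell_", seq_len(nrow(x)))
    return(x)
  }
  abort("Expected an `expr_matrix`, numeric matrix, or data frame.",
        class = "bifurscan_format_error")
}

unclass_expr <- function(x) {
  class(x) <- "matrix"
  attr(x, "pseudotime") <- NULL
  # drop to base matrix while keeping dimnames
  matrix(as.numeric(x), nrow(x), ncol(x), dimnames = dimnames(x))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d cells x %d genes%s\n", nrow(x), ncol(x),
              if (is.null(pseudotime(x))) "" else ", with pseudotime"))
  nr <- min(5L, nrow(x)); nc <- min(5L, ncol(x))
  print(unclass_expr(x)[seq_len(nr), seq_len(nc), drop = FALSE])
  invisible(x)
}

#' @export
#' @exportS3Method tibble::as_tibble
as_tibble.expr_matrix <- function(x, ...) {
  out <- tibble::as_tibble(unclass_expr(x), rownames = "cell")
  pt <- pseudotime(x)
  if (!is.null(pt)) out <- tibble::add_column(out, pseudotime = pt, .after = "cell")
  out
}
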