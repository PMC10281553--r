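#' Read an expression matrix
#'
#' Reads either a MatrixMarket coordinate file plus gene/cell label files,
#' or a dense delimited table (header = gene names, first column = cell id).
#' Cells are rows everywhere in this package; MatrixMarket inputs commonly
#' store genes x cells, so set `transpose = TRUE` for such files — if the
#' label lengths unambiguously indicate the other orientation the matrix is
#' transposed with a warning.
#'
#' @param path Path to the `.mtx` or delimited file.
#' @param format `"auto"` (by extension), `"mtx"`, or `"tsv"`.
#' @param genes,cells Paths to one-column label files (MatrixMarket only;
#'   the first column is used).
#' @param transpose Input is genes x cells. Default `FALSE`.
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path, format = c("auto", "mtx", "tsv"),
                                   genes = NULL, cells = NULL,
                                   transpose = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  }
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "bifurscan_io_error")
  }
  if (format == "mtx") {
    # readMM only warns on truncated entry lists; treat that as malformed too
    as_format_error <- function(c) {
      abort(sprintf("Malformed MatrixMarket file %s: %s", path, conditionMessage(c)),
            class = "bifurscan_format_error")
    }
    m <- tryCatch(as.matrix(Matrix::readMM(path)),
                  error = as_format_error, warning = as_format_error)
    gene_names <- if (!is.null(genes)) read_label_column(genes) else NULL
    cell_ids <- if (!is.null(cells)) read_label_column(cells) else NULL
    if (transpose) m <- t(m)
    if (!is.null(gene_names) && !is.null(cell_ids)) {
      if (nrow(m) != length(cell_ids) || ncol(m) != length(gene_names)) {
        if (nrow(m) == length(gene_names) && ncol(m) == length(cell_ids)) {
          warn("Label files indicate a genes x cells matrix; transposing.")
          m <- t(m)
        } else {
          abort(sprintf(
            "Label counts (%d cells, %d genes) do not match matrix dimensions %d x %d.",
            length(cell_ids), length(gene_names), nrow(m), ncol(m)),
            class = "bifurscan_format_error")
        }
      }
    }
    out <- expr_matrix(m, cell_ids = cell_ids, gene_names = gene_names)
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           name_repair = "minimal")
    gene_names <- names(tab)[-1L]
    if (anyDuplicated(gene_names)) {
      abort(sprintf("Duplicate gene names in %s: %s", path,
                    paste(unique(gene_names[duplicated(gene_names)]), collapse = ", ")),
            class = "bifurscan_format_error")
    }
    m <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(tab[[1L]])
    if (transpose) {
      gene_names <- rownames(m)
      m <- t(m)
    }
    out <- expr_matrix(m)
  }
  n_zero_cells <- sum(rowSums(out) == 0)
  n_zero_genes <- sum(colSums(out) == 0)
  if (n_zero_cells + n_zero_genes > 0) {
    message(sprintf("Read %d x %d matrix (%d all-zero cells, %d all-zero genes).",
                    nrow(out), ncol(out), n_zero_cells, n_zero_genes))
  }
  out
}

read_label_column <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Label file not found: %s", path), class = "bifurscan_io_error")
  }
  tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  as.character(tab[[1L]])
}

#' Write an expression matrix
#'
#' `"tsv"` writes a dense table (first column `cell`, one column per gene)
#' to `path`. `"mtx"` treats `path` as a directory and writes
#' `matrix.mtx`, `genes.tsv` and `cells.tsv` into it. Pseudotime, when
#' present, is written alongside as `pseudotime.tsv` (cell id, value).
#'
#' @param x An [expr_matrix()] (or matrix with dimnames).
#' @param path Output file (tsv) or directory (mtx).
#' @param format `"tsv"` (default) or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  m <- as_expr_values(x)
  pt <- if (inherits(x, "expr_matrix")) pseudotime(x) else NULL
  if (format == "tsv") {
    ensure_parent_dir(path)
    tab <- tibble::as_tibble(m, .name_repair = "minimal")
    tab <- tibble::add_column(tab, cell = rownames(m), .before = 1L)
    readr::write_tsv(tab, path, progress = FALSE)
    if (!is.null(pt)) {
      readr::write_tsv(tibble(cell = rownames(m), pseudotime = pt),
                       file.path(dirname(path), "pseudotime.tsv"),
                       progress = FALSE)
    }
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), file.path(path, "matrix.mtx"))
    readr::write_tsv(tibble(gene = colnames(m)), file.path(path, "genes.tsv"),
                     col_names = FALSE, progress = FALSE)
    readr::write_tsv(tibble(cell = rownames(m)), file.path(path, "cells.tsv"),
                     col_names = FALSE, progress = FALSE)
    if (!is.null(pt)) {
      readr::write_tsv(tibble(cell = rownames(m), pseudotime = pt),
                       file.path(path, "pseudotime.tsv"), progress = FALSE)
    }
  }
  invisible(path)
}

ensure_parent_dir <- function(path) {
  d <- dirname(path)
  if (!dir.exists(d)) {
    dir.create(d, recursive = TRUE)
    message(sprintf("Created output directory %s", d))
  }
  invisible(d)
}

#' Read a pseudotime table
#'
#' Two-column delimited file (cell id, pseudotime value), header optional.
#' When `cell_ids` is supplied the mapping must cover every cell.
#'
#' @param path Path to the table.
#' @param cell_ids Optional cell ids to validate against.
#' @return Named numeric vector of pseudotimes.
#' @export
read_pseudotime <- function(path, cell_ids = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "bifurscan_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    abort(sprintf("Empty pseudotime file: %s", path), class = "bifurscan_format_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  first <- fields[[1L]]
  if (length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2L])))) {
    start <- 2L  # header row
  }
  ids <- character(0); vals <- numeric(0)
  for (i in seq.int(start, length(lines))) {
    f <- fields[[i]]
    if (length(f) < 2L) {
      abort(sprintf("Line %d of %s has fewer than 2 tab-separated fields.", i, path),
            class = "bifurscan_format_error")
    }
    v <- suppressWarnings(as.numeric(f[2L]))
    if (is.na(v)) {
      abort(sprintf("Non-numeric pseudotime '%s' at line %d of %s.", f[2L], i, path),
            class = "bifurscan_format_error")
    }
    ids <- c(ids, f[1L]); vals <- c(vals, v)
  }
  pt <- setNames(vals, ids)
  if (!is.null(cell_ids)) {
    missing <- setdiff(cell_ids, ids)
    if (length(missing) > 0L) {
      abort(sprintf("Pseudotime missing for cells: %s",
                    paste(head(missing, 10L), collapse = ", ")),
            class = "bifurscan_mapping_error")
    }
    pt <- pt[cell_ids]
  }
  pt
}

#' Read gene sets from a GMT file
#'
#' Tab-separated GMT dialect: set name, description, then member gene
#' symbols. Parsed with `fgsea::gmtPathways()`.
#'
#' @param path Path to the `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "bifurscan_io_error")
  }
  fgsea::gmtPathways(path)
}

#' Write scan results and transition report to disk
#'
#' Writes the per-bin scan table as TSV (numbers rounded to 10 significant
#' digits so repeated runs are byte-identical) and the transition report as
#' JSON. Refuses incomplete inputs, naming the missing stage.
#'
#' @param scan An [scan_trajectory()] result.
#' @param report A [classify_transitions()] result.
#' @param scan_path Output TSV path.
#' @param report_path Output JSON path.
#' @return Invisibly, the two paths.
#' @export
write_scan_outputs <- function(scan, report, scan_path, report_path) {
  required <- c("bin", "n_cells", "mean_pseudotime", "omega1", "omega1_shifted",
                "null_mean", "null_sd", "z")
  missing <- setdiff(required, names(scan))
  if (length(missing) > 0L) {
    stage <- if (any(c("null_mean", "null_sd", "z") %in% missing)) "null" else "omega"
    abort(sprintf("Scan results incomplete: missing %s stage columns (%s).",
                  stage, paste(missing, collapse = ", ")),
          class = "bifurscan_partial_results")
  }
  if (!inherits(report, "transition_report")) {
    abort("Scan results incomplete: missing classification stage.",
          class = "bifurscan_partial_results")
  }
  ensure_parent_dir(scan_path)
  ensure_parent_dir(report_path)
  out <- mutate(as_tibble(scan),
                dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 10L)))
  readr::write_tsv(out, scan_path, progress = FALSE)
  jsonlite::write_json(
    list(events = as_tibble(report),
         thresholds = attr(report, "thresholds") %||% list()),
    report_path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(c(scan_path, report_path))
}
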