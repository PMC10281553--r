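#' Principal covariance eigenvector per pseudotime bin
#'
#' Computes the unit-norm principal covariance eigenvector of every bin
#' (sign-fixed so the largest-magnitude loading is positive), with a
#' consistent gene ordering across bins.
#'
#' @inheritParams omega_trajectory
#' @return An object of class `eigvec_series`: list with `loadings`
#'   (genes x bins matrix, unit columns), `bins` (labels), `gene_names`,
#'   `mean_pseudotime`.
#' @export
eigvec_series <- function(x, bins) {
  m <- as_expr_values(x)
  check_bins(bins, nrow(m))
  L <- vapply(bins$cells, function(idx) {
    covariance_eig(m[idx, , drop = FALSE], k = 1L)$vectors[, 1L]
  }, numeric(ncol(m)))
  L <- matrix(L, nrow = ncol(m),
              dimnames = list(colnames(m), paste0("bin", bins$bin)))
  structure(
    list(loadings = L, bins = bins$bin, gene_names = colnames(m),
         mean_pseudotime = bins$mean_pseudotime),
    class = "eigvec_series"
  )
}

#' @export
print.eigvec_series <- function(x, ...) {
  cat(sprintf("<eigvec_series> %d genes x %d bins\n",
              nrow(x$loadings), ncol(x$loadings)))
  invisible(x)
}

#' @describeIn eigvec_series Long tibble: bin, gene, loading.
#' @param x An `eigvec_series`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.eigvec_series <- function(x, ...) {
  tibble(
    bin = rep(x$bins, each = nrow(x$loadings)),
    gene = rep(x$gene_names, times = ncol(x$loadings)),
    loading = as.vector(x$loadings)
  )
}

#' Bin-by-bin correlation map of principal eigenvectors
#'
#' Pearson correlation between the loading profiles of every pair of bins.
#' Blocks of high correlation indicate pseudotime epochs sharing one
#' bifurcation direction; block boundaries line up with transition events.
#'
#' @param series An [eigvec_series()], or a genes-x-bins loading matrix.
#' @param absolute Correlate absolute loadings instead of raw ones.
#'   Default `FALSE`.
#' @return A bins-x-bins correlation matrix of class `eigvec_cormap`
#'   (symmetric, unit diagonal).
#' @export
eigvec_correlation_map <- function(series, absolute = FALSE) {
  L <- if (inherits(series, "eigvec_series")) series$loadings else as.matrix(series)
  if (ncol(L) < 2L) {
    abort("At least 2 bins are required for a correlation map.",
          class = "bifurscan_config_error")
  }
  if (anyNA(L)) {
    abort("Loadings contain missing values; gene sets are misaligned.",
          class = "bifurscan_alignment_error")
  }
  if (absolute) L <- abs(L)
  R <- cor(L)
  diag(R) <- 1
  structure(R, class = c("eigvec_cormap", "matrix"))
}

#' Project cells onto a direction in gene space
#'
#' Dot product of each cell's (normalized) expression row with a unit
#' vector; the canonical low-dimensional coordinate near a bifurcation,
#' where the principal covariance eigenvector is the bifurcation direction.
#' No centering is applied unless requested.
#'
#' @inheritParams covariance_eig
#' @param vector Numeric direction of length `n_genes`; normalized to unit
#'   norm internally.
#' @param center Subtract gene means before projecting. Default `FALSE`.
#' @return Tibble: `cell`, `projection`.
#' @export
project_cells <- function(x, vector, center = FALSE) {
  m <- as_expr_values(x)
  if (length(vector) != ncol(m)) {
    abort(sprintf("`vector` must have length %d (gene count).", ncol(m)),
          class = "bifurscan_shape_error")
  }
  nv <- sqrt(sum(vector^2))
  if (nv == 0) abort("`vector` must be nonzero.", class = "bifurscan_domain_error")
  v <- vector / nv
  if (center) m <- sweep(m, 2L, colMeans(m))
  tibble(cell = rownames(m), projection = as.vector(m %*% v))
}

#' Per-bin projection distributions and bimodality flags
#'
#' Projects every bin's cells onto a fixed direction and summarizes the
#' per-bin distribution. Bimodality is flagged when a two-component 1-D
#' Gaussian mixture is preferred over a single component by more than
#' `delta_bic` (mclust's BIC, larger is better).
#'
#' @inheritParams omega_trajectory
#' @param vector Direction in gene space (normalized internally).
#' @param delta_bic Evidence threshold for bimodality. Default 10.
#' @return Tibble: `bin`, `n_cells`, `mean`, `sd`, `q25`, `q75`,
#'   `delta_bic`, `bimodal`.
#' @export
projection_distribution <- function(x, bins, vector, delta_bic = 10) {
  m <- as_expr_values(x)
  check_bins(bins, nrow(m))
  proj <- project_cells(m, vector)$projection
  rows <- purrr::map2(bins$cells, bins$bin, function(idx, b) {
    p <- proj[idx]
    db <- mixture_evidence(p)
    flag <- is.finite(db) && db > delta_bic
    tibble(bin = b, n_cells = length(p), mean = mean(p), sd = sd(p),
           q25 = quantile(p, 0.25, names = FALSE),
           q75 = quantile(p, 0.75, names = FALSE),
           delta_bic = db, bimodal = flag)
  })
  bind_rows(rows)
}

# BIC evidence for 2 vs 1 Gaussian components in 1-D (mclust convention:
# larger BIC is better). Returns -Inf for degenerate input.
mixture_evidence <- function(p) {
  if (length(p) < 10L || sd(p) <= .Machine$double.eps) return(-Inf)
  fit <- mclust::mclustBIC(p, G = 1:2, verbose = FALSE)
  b1 <- suppressWarnings(max(fit[1L, ], na.rm = TRUE))
  b2 <- suppressWarnings(max(fit[2L, ], na.rm = TRUE))
  if (!is.finite(b1) || !is.finite(b2)) return(-Inf)
  b2 - b1
}

#' Fraction of total variance along a direction
#'
#' Variance of the centered projections divided by the total variance (sum
#' of per-gene variances). Equals `omega1 / sum(omega_i)` when `vector` is
#' the principal covariance eigenvector, and is bounded by it for any other
#' unit vector (Rayleigh quotient).
#'
#' @inheritParams project_cells
#' @return Scalar in `[0, 1]`.
#' @export
variance_fraction <- function(x, vector) {
  m <- as_expr_values(x)
  total <- sum(apply(m, 2L, var))
  if (total <= 0) {
    abort("Total variance is zero.", class = "bifurscan_domain_error")
  }
  v <- vector / sqrt(sum(vector^2))
  var(as.vector(m %*% v)) / total
}

#' Average gene-set weights of an eigenvector
#'
#' For each gene set (category) `c`, the mean absolute loading of its
#' member genes in the eigenvector: `W_c = mean(|s_g|, g in G_c)`. Genes
#' absent from the vector are ignored and counted; categories matching
#' fewer than `min_size` genes are dropped. With `signed = TRUE` the plain
#' mean of signed loadings is returned instead.
#'
#' @param vector Named numeric vector of loadings (names = genes), or an
#'   unnamed vector with `gene_names` supplied.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gene_sets()]).
#' @param gene_names Gene names for an unnamed `vector`.
#' @param min_size Minimum matched genes per category. Default 1.
#' @param signed Use signed loadings. Default `FALSE`.
#' @return Tibble sorted by decreasing weight: `category`, `weight`,
#'   `n_genes` (matched), `n_unmatched`.
#' @export
#' @examples
#' category_weights(c(a = 0.6, b = -0.8), list(set1 = c("a", "b")))
category_weights <- function(vector, gene_sets, gene_names = NULL,
                             min_size = 1L, signed = FALSE) {
  if (length(gene_sets) == 0L) {
    abort("`gene_sets` must be nonempty.", class = "bifurscan_set_error")
  }
  if (!is.null(gene_names)) names(vector) <- gene_names
  if (is.null(names(vector))) {
    abort("`vector` must be named by gene (or supply `gene_names`).",
          class = "bifurscan_config_error")
  }
  rows <- purrr::imap(gene_sets, function(genes, cat) {
    hit <- intersect(genes, names(vector))
    tibble(category = cat,
           weight = if (length(hit) == 0L) NA_real_ else {
             s <- vector[hit]
             if (signed) mean(s) else mean(abs(s))
           },
           n_genes = length(hit),
           n_unmatched = length(genes) - length(hit))
  })
  out <- filter(bind_rows(rows), .data$n_genes >= min_size)
  if (nrow(out) == 0L) {
    abort(sprintf("No category matches at least %d genes.", min_size),
          class = "bifurscan_set_error")
  }
  arrange(out, dplyr::desc(.data$weight))
}
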