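#' Covariance eigendecomposition via reduced SVD
#'
#' Column-centers the expression matrix and computes the top-`k` covariance
#' eigenvalues and eigenvectors from the singular value decomposition:
#' `omega_i = d_i^2 / (n_cells - 1)` with the unbiased `n - 1` divisor, and
#' eigenvectors equal to the right singular vectors, sign-fixed so the
#' largest-magnitude loading is positive. Equivalent to eigendecomposing
#' the sample covariance, but never forms the gene-by-gene matrix.
#'
#' @param x An [expr_matrix()], numeric matrix, or data frame with cells in
#'   rows and genes in columns (first column = cell id for data frames).
#' @param k Number of components to return; default all
#'   (`min(n_cells - 1, n_genes)`).
#' @return An object of class `cov_eig`: list with `values` (descending,
#'   nonnegative), `vectors` (genes x k, unit columns), `n_cells`,
#'   `gene_names`. `tidy()` gives the long loading table, `glance()` the
#'   spectrum summary.
#' @export
#' @examples
#' m <- matrix(c(0, 0, 1, 2, 2, 4, 3, 6), 4, 2, byrow = TRUE)
#' covariance_eig(m)$values  # 25/3, 0
covariance_eig <- function(x, k = NULL) {
  m <- as_expr_values(x)
  n <- nrow(m)
  if (n < 2L) {
    abort("Covariance is undefined for fewer than 2 cells.",
          class = "bifurscan_undefined_covariance")
  }
  k_max <- min(n - 1L, ncol(m))
  k <- as.integer(k %||% k_max)
  if (k < 1L) abort("`k` must be at least 1.", class = "bifurscan_config_error")
  k <- min(k, k_max)
  xc <- sweep(m, 2L, colMeans(m))
  sv <- svd(xc, nu = 0, nv = k)
  values <- sv$d^2 / (n - 1)
  values <- values[seq_len(k)]
  vectors <- apply(sv$v, 2L, fix_sign)
  vectors <- matrix(vectors, ncol = k,
                    dimnames = list(colnames(m), paste0("s", seq_len(k))))
  structure(
    list(values = values, vectors = vectors, n_cells = n,
         gene_names = colnames(m)),
    class = "cov_eig"
  )
}

#' @export
print.cov_eig <- function(x, ...) {
  cat(sprintf("<cov_eig> %d components from %d cells x %d genes; omega1 = %.4g\n",
              length(x$values), x$n_cells, length(x$gene_names), x$values[1L]))
  invisible(x)
}

#' @describeIn covariance_eig Long tibble of loadings: gene, component,
#'   loading.
#' @param x A `cov_eig` object.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.cov_eig <- function(x, ...) {
  tibble(
    gene = rep(x$gene_names, times = ncol(x$vectors)),
    component = rep(seq_len(ncol(x$vectors)), each = length(x$gene_names)),
    loading = as.vector(x$vectors)
  )
}

#' @describeIn covariance_eig One-row spectrum summary: `omega1`, total
#'   returned variance, fraction in the first component, `n_cells`.
#' @export
#' @exportS3Method generics::glance
glance.cov_eig <- function(x, ...) {
  tibble(omega1 = x$values[1L], total_variance = sum(x$values),
         frac_omega1 = x$values[1L] / max(sum(x$values), .Machine$double.eps),
         n_components = length(x$values), n_cells = x$n_cells)
}

#' Pairwise Pearson correlation matrix with zero-variance handling
#'
#' Computes the gene-by-gene Pearson correlation matrix. Genes with zero
#' variance get `NA` rows/columns and are excluded from the off-diagonal
#' value distribution (their count is recorded).
#'
#' @inheritParams covariance_eig
#' @return An object of class `pearson_cor`: list with `R` (correlation
#'   matrix, `NA` for undefined pairs) and `zero_variance` (gene names).
#'   `tidy()` returns the off-diagonal pair table (each unordered pair
#'   once).
#' @export
pearson_matrix <- function(x) {
  m <- as_expr_values(x)
  if (nrow(m) < 3L) {
    abort("At least 3 cells are required for correlation estimates.",
          class = "bifurscan_undefined_covariance")
  }
  v <- apply(m, 2L, var)
  zero <- colnames(m)[v <= .Machine$double.eps]
  if (length(zero) == ncol(m)) {
    abort("All genes have zero variance; correlation distribution is empty.",
          class = "bifurscan_empty_distribution")
  }
  R <- matrix(NA_real_, ncol(m), ncol(m), dimnames = list(colnames(m), colnames(m)))
  ok <- setdiff(colnames(m), zero)
  R[ok, ok] <- cor(m[, ok, drop = FALSE])
  structure(list(R = R, zero_variance = zero), class = "pearson_cor")
}

#' @export
print.pearson_cor <- function(x, ...) {
  cat(sprintf("<pearson_cor> %d genes (%d with zero variance excluded)\n",
              ncol(x$R), length(x$zero_variance)))
  invisible(x)
}

#' @describeIn pearson_matrix Tibble of unordered gene pairs and their
#'   correlations, defined pairs only.
#' @param x A `pearson_cor` object.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.pearson_cor <- function(x, ...) {
  idx <- which(upper.tri(x$R), arr.ind = TRUE)
  out <- tibble(
    gene_i = rownames(x$R)[idx[, 1L]],
    gene_j = colnames(x$R)[idx[, 2L]],
    r = x$R[idx]
  )
  dplyr::filter(out, !is.na(.data$r))
}

#' Sign-aligned Euclidean distance between eigenvectors
#'
#' Both vectors are normalized to unit norm; the sign of `v_b` is flipped if
#' that reduces the distance (eigenvectors are defined up to sign). The
#' result lies in `[0, sqrt(2)]`, with 0 for (anti-)parallel vectors and
#' `sqrt(2)` for orthogonal ones.
#'
#' @param v_a,v_b Numeric vectors of equal length, nonzero.
#' @return Scalar distance.
#' @export
#' @examples
#' eigvec_alignment(c(1, 0), c(-1, 0))  # 0
eigvec_alignment <- function(v_a, v_b) {
  if (length(v_a) != length(v_b)) {
    abort("Vectors must have equal length.", class = "bifurscan_shape_error")
  }
  na <- sqrt(sum(v_a^2)); nb <- sqrt(sum(v_b^2))
  if (na == 0 || nb == 0) {
    abort("Vectors must be nonzero.", class = "bifurscan_domain_error")
  }
  a <- v_a / na; b <- v_b / nb
  sqrt(min(sum((a - b)^2), sum((a + b)^2)))
}

#' Responder-driver correlations sorted by coupling strength
#'
#' For each responder gene, the Pearson correlation between its expression
#' and its own driver's, paired with the coupling strength `alpha`. Near the
#' bifurcation these correlations become strongly indicative of the
#' coupling: activating responders (`alpha` near 1) correlate positively
#' with their driver, inhibited ones (`alpha` near 0) negatively.
#'
#' @param x Expression matrix produced by [grn_simulate()] with `params`.
#' @param params The matching [grn_network()] parameter object.
#' @return Tibble sorted by `alpha`: `gene`, `driver`, `alpha`, `r` (`NA`
#'   when either gene has zero variance).
#' @export
driver_responder_correlations <- function(x, params) {
  m <- as_expr_values(x)
  if (!identical(colnames(m), params$gene_names)) {
    abort("Gene names of the matrix do not match `params`.",
          class = "bifurscan_mapping_error")
  }
  n_resp <- params$n_genes - 2L
  if (n_resp == 0L) {
    return(tibble(gene = character(), driver = integer(),
                  alpha = numeric(), r = numeric()))
  }
  v <- apply(m, 2L, var)
  r <- vapply(seq_len(n_resp), function(i) {
    gi <- i + 2L
    gd <- params$driver_of[i]
    if (v[gi] <= .Machine$double.eps || v[gd] <= .Machine$double.eps) {
      return(NA_real_)
    }
    cor(m[, gi], m[, gd])
  }, numeric(1))
  arrange(
    tibble(gene = params$gene_names[-(1:2)], driver = params$driver_of,
           alpha = params$alpha, r = r),
    .data$alpha
  )
}
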