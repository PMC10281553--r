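#' Two-component Gaussian-mixture split of a bin
#'
#' Fits a two-component Gaussian mixture to the cells of a (bifurcating)
#' bin to separate coexisting transcriptomic modes. By default the fit is
#' performed in the top-`d` principal subspace of the bin with diagonal
#' component covariances, which keeps the model well conditioned in high
#' dimension; `method = "full"` fits diagonal-covariance components in the
#' full gene space instead. The fit is deterministic given `seed`.
#'
#' @inheritParams covariance_eig
#' @param d Dimension of the principal subspace. Default 10 (reduced to the
#'   available rank).
#' @param method `"pca"` (default) or `"full"`.
#' @param seed RNG seed (mclust initialization is deterministic, but the
#'   seed is fixed for byte-stable output regardless).
#' @return An object of class `mixture_split`: list with `model` (the
#'   mclust fit), `center`, `rotation` (or `NULL` for `"full"`), `labels`
#'   (tibble `cell`, `label` in `{"a","b"}`, `posterior`), `separation`
#'   (distance between component means in pooled-sd units), `delta_bic`
#'   (evidence for 2 vs 1 components), `gene_names`, `seed`.
#' @export
fit_mixture_split <- function(x, d = 10L, method = c("pca", "full"), seed = 1L) {
  method <- match.arg(method)
  m <- as_expr_values(x)
  if (nrow(m) < 20L) {
    abort("At least 20 cells are required for a mixture split.",
          class = "bifurscan_config_error")
  }
  if (all(apply(m, 2L, var) <= .Machine$double.eps)) {
    abort("Input has zero variance in every gene; mixture fit is degenerate.",
          class = "bifurscan_degeneracy_error")
  }
  center <- colMeans(m)
  xc <- sweep(m, 2L, center)
  rotation <- NULL
  if (method == "pca") {
    sv <- svd(xc, nu = 0)
    rank <- sum(sv$d > sv$d[1L] * 1e-10)
    d <- min(as.integer(d), rank)
    rotation <- sv$v[, seq_len(d), drop = FALSE]
    rownames(rotation) <- colnames(m)
    scores <- xc %*% rotation
  } else {
    scores <- xc
  }
  # diagonal-covariance family; the best member by BIC is used (the
  # restricted spherical models are much more robust to bad EM starts in
  # the presence of many noise dimensions)
  model_names <- if (ncol(scores) == 1L) c("E", "V") else {
    c("EII", "VII", "EEI", "VEI", "EVI", "VVI")
  }
  fit <- with_seed(seed, mclust::Mclust(scores, G = 2, modelNames = model_names,
                                        verbose = FALSE))
  if (is.null(fit)) {
    abort("Mixture fit failed to converge.", class = "bifurscan_degeneracy_error")
  }
  bic <- with_seed(seed, mclust::mclustBIC(scores, G = 1:2,
                                           modelNames = model_names,
                                           verbose = FALSE))
  delta_bic <- suppressWarnings(max(bic[2L, ], na.rm = TRUE) -
                                  max(bic[1L, ], na.rm = TRUE))
  # component "a" = larger mixing weight; ties broken by smaller first mean
  pro <- fit$parameters$pro
  mu <- fit$parameters$mean
  first <- if (abs(pro[1L] - pro[2L]) > 1e-12) which.max(pro) else which.min(mu[1L, ])
  comp_label <- c("b", "b"); comp_label[first] <- "a"
  post <- fit$z
  labels <- tibble(
    cell = rownames(m),
    label = comp_label[fit$classification],
    posterior = post[cbind(seq_len(nrow(post)), fit$classification)]
  )
  dmu <- mu[, 1L] - mu[, 2L]
  pooled <- (diag_of_variance(fit, 1L) + diag_of_variance(fit, 2L)) / 2
  separation <- sqrt(mean(dmu^2 / pmax(pooled, .Machine$double.eps)))
  structure(
    list(model = fit, center = center, rotation = rotation, labels = labels,
         comp_label = comp_label, separation = separation,
         delta_bic = delta_bic, gene_names = colnames(m),
         method = method, seed = seed),
    class = "mixture_split"
  )
}

diag_of_variance <- function(fit, k) {
  sig <- fit$parameters$variance$sigma
  if (is.null(sig)) {
    # 1-D models store sigmasq
    s2 <- fit$parameters$variance$sigmasq
    return(if (length(s2) == 1L) s2 else s2[k])
  }
  diag(sig[, , k])
}

#' @export
print.mixture_split <- function(x, ...) {
  cat(sprintf("<mixture_split> %d cells, %s space; separation %.2f, delta BIC %.1f\n",
              nrow(x$labels),
              if (x$method == "pca") sprintf("%d-PC", ncol(x$rotation)) else "full",
              x$separation, x$delta_bic))
  print(table(x$labels$label))
  invisible(x)
}

#' @describeIn fit_mixture_split Per-cell label table.
#' @param x A `mixture_split`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.mixture_split <- function(x, ...) x$labels

#' @describeIn fit_mixture_split One-row fit summary.
#' @export
#' @exportS3Method generics::glance
glance.mixture_split <- function(x, ...) {
  tibble(n_cells = nrow(x$labels),
         frac_a = mean(x$labels$label == "a"),
         separation = x$separation, delta_bic = x$delta_bic,
         dim = if (x$method == "pca") ncol(x$rotation) else length(x$gene_names))
}

#' Propagate mixture labels along the whole trajectory
#'
#' Assigns every cell in every bin to the nearest fitted component (by
#' posterior probability under the trained model, after projecting through
#' the stored centering/rotation) and reports the per-bin label composition
#' together with per-cluster principal covariance eigenvalues. Splitting a
#' pitchfork's branches this way recovers the per-branch bifurcation
#' signature that pooling washes out.
#'
#' @param split A [fit_mixture_split()] result.
#' @inheritParams omega_trajectory
#' @return Tibble: `bin`, `n_cells`, `frac_a`, `frac_b`, `omega1_a`,
#'   `omega1_b` (`NA` when a cluster has fewer than 2 cells in the bin).
#'   Per-cell assignments are attached as attribute `"cell_labels"`.
#' @export
propagate_labels <- function(split, x, bins) {
  m <- as_expr_values(x)
  if (!identical(colnames(m), split$gene_names)) {
    abort("Gene names do not match the fitted mixture model.",
          class = "bifurscan_mapping_error")
  }
  check_bins(bins, nrow(m))
  xc <- sweep(m, 2L, split$center)
  scores <- if (!is.null(split$rotation)) xc %*% split$rotation else xc
  pred <- mclust::predict.Mclust(split$model, newdata = scores)
  labels <- split$comp_label[pred$classification]
  cell_labels <- tibble(cell = rownames(m), label = labels)
  rows <- purrr::map2(bins$cells, bins$bin, function(idx, b) {
    lab <- labels[idx]
    om <- vapply(c("a", "b"), function(cl) {
      sel <- idx[lab == cl]
      if (length(sel) < 2L) return(NA_real_)
      covariance_eig(m[sel, , drop = FALSE], k = 1L)$values[1L]
    }, numeric(1))
    tibble(bin = b, n_cells = length(idx),
           frac_a = mean(lab == "a"), frac_b = mean(lab == "b"),
           omega1_a = om[["a"]], omega1_b = om[["b"]])
  })
  out <- bind_rows(rows)
  attr(out, "cell_labels") <- cell_labels
  out
}
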