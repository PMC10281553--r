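#' Plot an eigenvalue scan
#'
#' Shifted principal covariance eigenvalue per bin (solid), the
#' gene-shuffled null with a +/- 1 sd ribbon (grey), optional DNB index
#' (dashed, rescaled to the eigenvalue range), and detected transition
#' events as vertical lines.
#'
#' @param object An [scan_trajectory()] result.
#' @param report Optional [classify_transitions()] result to mark events.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.omega_scan <- function(object, report = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$null_mean_shifted - .data$null_sd,
      ymax = .data$null_mean_shifted + .data$null_sd),
      fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_mean_shifted), colour = "grey45") +
    ggplot2::geom_line(ggplot2::aes(y = .data$omega1_shifted), linewidth = 0.8) +
    ggplot2::labs(x = "pseudotime bin",
                  y = expression(omega[1] ~ "(min-shifted)")) +
    ggplot2::theme_minimal()
  if ("dnb" %in% names(df) && any(is.finite(df$dnb))) {
    scale <- max(df$omega1_shifted) / max(df$dnb, na.rm = TRUE)
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$dnb * !!scale),
                                linetype = "dashed", colour = "purple")
  }
  if (!is.null(report) && nrow(report) > 0L) {
    p <- p + ggplot2::geom_vline(data = as_tibble(report),
                                 ggplot2::aes(xintercept = .data$bin),
                                 linetype = "dotted", colour = "darkgreen")
  }
  p
}

#' Plot an eigenvector correlation map
#'
#' Heatmap of the bin-by-bin Pearson correlations between principal
#' covariance eigenvectors; block structure marks epochs sharing one
#' bifurcation direction.
#'
#' @param object An [eigvec_correlation_map()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.eigvec_cormap <- function(object, ...) {
  R <- unclass(object)
  df <- tibble(
    bin_i = rep(seq_len(nrow(R)), times = ncol(R)),
    bin_j = rep(seq_len(ncol(R)), each = nrow(R)),
    r = as.vector(R)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_i, .data$bin_j, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "bin", y = "bin",
                  fill = expression(rho(hat(s)[1]))) +
    ggplot2::theme_minimal()
}

#' Plot a control-parameter sweep
#'
#' Min-max-normalized mean steady-state expression of every gene against
#' the control value, genes ordered by driver assignment and coupling
#' strength; drivers switch discontinuously at the saddle-node and
#' responders follow their driver according to `alpha`.
#'
#' @param object A [grn_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.grn_sweep <- function(object, ...) {
  params <- attr(object, "params")
  control <- attr(object, "control")
  means <- purrr::map2(object$matrix, object$control_value, function(m, v) {
    tibble(control_value = v, gene = colnames(m), mean_expr = colMeans(m))
  })
  df <- bind_rows(means)
  df <- group_by(df, .data$gene)
  df <- mutate(df, norm = (.data$mean_expr - min(.data$mean_expr)) /
                 max(diff(range(.data$mean_expr)), .Machine$double.eps))
  df <- ungroup(df)
  ord <- tidy(params)
  ord <- ord[order(ord$role == "responder", ord$driver, ord$alpha), ]
  df$gene <- factor(df$gene, levels = ord$gene)
  ggplot2::ggplot(df, ggplot2::aes(.data$control_value, .data$gene,
                                   fill = .data$norm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "min-max\nexpression") +
    ggplot2::labs(x = control, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot per-bin projection distributions
#'
#' Mean and interquartile band of the projection coordinate per bin, with
#' bins flagged as bimodal marked.
#'
#' @param dist A [projection_distribution()] result.
#' @return A ggplot object.
#' @export
plot_projection_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::geom_point(data = dplyr::filter(dist, .data$bimodal),
                        ggplot2::aes(y = .data$mean), colour = "red") +
    ggplot2::labs(x = "pseudotime bin", y = "projection") +
    ggplot2::theme_minimal()
}
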