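#' Generate a synthetic trajectory with a planted transition
#'
#' Builds a pseudotime-ordered expression matrix whose cells are drawn,
#' group by group, from a Gaussian with a planted covariance: isotropic
#' baseline noise plus a rank-1 component along a fixed nonnegative unit
#' direction whose magnitude follows the transition class —
#' a delta at the transition group (`"one-to-one"`, the saddle-node
#' signature), a linear ramp from it (`"one-to-many"`, the pitchfork
#' signature), a level shift (`"step-like"`, the noise-induced-transition
#' signature), or absent throughout (`"none"`). Values are shifted to a
#' positive baseline and clamped at zero, so the planted covariance holds
#' to excellent approximation. The ground truth (direction, groups,
#' transition group) is attached for assertions.
#'
#' @param n_cells,n_genes Matrix dimensions. Defaults 3000 x 40.
#' @param n_groups Number of consecutive pseudotime groups the planted
#'   structure is defined over. Default 30.
#' @param transition_group Group at which the transition is planted.
#'   Default `n_groups / 2`.
#' @param class Transition class.
#' @param effect Rank-1 magnitude in units of the baseline noise sd.
#'   Default 10.
#' @param noise Baseline noise sd. Default 1.
#' @param baseline Mean expression in noise-sd units (keeps values away
#'   from the nonnegativity clamp). Default 8.
#' @param seed RNG seed.
#' @return An [expr_matrix()] with pseudotime in `[0, 1]` and attribute
#'   `"truth"`: list with `direction`, `group` (per cell),
#'   `transition_group`, `class`, `effect`, `noise`, `magnitude` (per
#'   group).
#' @export
generate_fixture <- function(n_cells = 3000L, n_genes = 40L, n_groups = 30L,
                             transition_group = NULL,
                             class = c("none", "one-to-one", "one-to-many", "step-like"),
                             effect = 10, noise = 1, baseline = 8, seed = 1L) {
  class <- match.arg(class)
  transition_group <- as.integer(transition_group %||% max(1L, n_groups %/% 2L))
  if (transition_group < 1L || transition_group > n_groups) {
    abort("`transition_group` must lie within 1..n_groups.",
          class = "bifurscan_config_error")
  }
  if (effect < 0) abort("`effect` must be nonnegative.", class = "bifurscan_config_error")
  sizes <- diff(round(seq(0, n_cells, length.out = n_groups + 1L)))
  group <- rep(seq_len(n_groups), times = sizes)
  a <- effect * noise
  magnitude <- switch(
    class,
    "none" = rep(0, n_groups),
    "one-to-one" = ifelse(seq_len(n_groups) == transition_group, a, 0),
    "one-to-many" = {
      g <- seq_len(n_groups)
      ifelse(g >= transition_group,
             a * (g - transition_group + 1L) / (n_groups - transition_group + 1L), 0)
    },
    "step-like" = ifelse(seq_len(n_groups) >= transition_group, a, 0)
  )
  with_seed(seed, {
    v <- abs(rnorm(n_genes))
    v <- v / sqrt(sum(v^2))
    X <- baseline * noise + noise * matrix(rnorm(n_cells * n_genes), n_cells, n_genes)
    amp <- magnitude[group] * rnorm(n_cells)
    X <- X + amp %o% v
    X[X < 0] <- 0
    out <- expr_matrix(X, cell_ids = paste0("cell_", seq_len(n_cells)),
                       gene_names = paste0("gene_", seq_len(n_genes)),
                       pseudotime = (seq_len(n_cells) - 0.5) / n_cells)
    attr(out, "truth") <- list(direction = v, group = group,
                               transition_group = transition_group,
                               class = class, effect = effect, noise = noise,
                               magnitude = magnitude)
    out
  })
}
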