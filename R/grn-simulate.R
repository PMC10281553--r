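#' Simulate the stochastic toggle-switch network
#'
#' Euler–Maruyama integration of the network for `n_cells` independent cells.
#' Each gene is initialized uniformly in `init_range`; at every step the new
#' expression is sampled from `Normal(g + dt * drift, sigma)` and clamped at
#' zero, with chemical-Langevin-style per-gene noise
#' `sigma^2 = dt * (synthesis + degradation) * noise` (so Poisson-like:
#' variance proportional to total reaction flux). The final step is returned
#' as the steady-state expression matrix. Fully reproducible given `seed`.
#'
#' @param params A [grn_network()] parameter object.
#' @param seed RNG seed; defaults to `params$seed`.
#' @param drift_warn_tol Warn if the mean max-norm drift over the final 1%
#'   of steps exceeds this value (equilibration check). Default 1.
#' @return An [expr_matrix()] of dimension `n_cells` x `n_genes`.
#' @export
#' @examples
#' net <- grn_network(n_genes = 4, n_cells = 20, n_steps = 2000, seed = 1)
#' G <- grn_simulate(net)
grn_simulate <- function(params, seed = NULL, drift_warn_tol = 1) {
  seed <- seed %||% params$seed
  n_c <- params$n_cells; n_g <- params$n_genes
  n_resp <- n_g - 2L
  dt <- params$dt; inv_s <- params$noise
  kd <- params$k_d
  # per-column parameter matrices so the inner loop is pure elementwise algebra
  K <- matrix(rep(c(kd, kd, params$k_resp), each = n_c), n_c, n_g)
  if (n_resp > 0L) {
    A  <- matrix(rep(params$alpha, each = n_c), n_c, n_resp)
    Md <- matrix(rep(c(params$m1, params$m2)[params$driver_of], each = n_c), n_c, n_resp)
    drv <- params$driver_of
  }
  with_seed(seed, {
    G <- matrix(runif(n_c * n_g, params$init_range[1], params$init_range[2]), n_c, n_g)
    syn <- matrix(0, n_c, n_g)
    tail_start <- max(1L, params$n_steps - ceiling(params$n_steps / 100) + 1L)
    tail_drift <- 0; tail_n <- 0L
    for (step in seq_len(params$n_steps)) {
      syn[, 1L] <- params$m1 / (1 + G[, 2L]^2)
      syn[, 2L] <- params$m2 / (1 + G[, 1L]^2)
      if (n_resp > 0L) {
        Gd <- G[, drv, drop = FALSE]
        denom <- 1 + Gd^2
        syn[, -(1:2)] <- Md * (A * Gd^2 + (1 - A)) / denom
      }
      deg <- K * G
      drift <- syn - deg
      if (step >= tail_start) {
        tail_drift <- tail_drift + mean(apply(abs(drift), 1L, max))
        tail_n <- tail_n + 1L
      }
      mu <- G + dt * drift
      if (inv_s > 0) {
        sig <- sqrt(dt * (syn + deg) * inv_s)
        G <- mu + sig * matrix(rnorm(n_c * n_g), n_c, n_g)
      } else {
        G <- mu
      }
      if (anyNA(G) || any(!is.finite(G))) {
        abort(sprintf("Integration became non-finite at step %d.", step),
              class = "bifurscan_instability_error")
      }
      G[G < 0] <- 0
    }
    if (tail_n > 0L && tail_drift / tail_n > drift_warn_tol) {
      warn(sprintf(
        "Mean drift max-norm %.3g over the final 1%% of steps exceeds %g; consider more steps.",
        tail_drift / tail_n, drift_warn_tol))
    }
    expr_matrix(G, cell_ids = paste0("cell_", seq_len(n_c)),
                gene_names = params$gene_names)
  })
}

#' Sweep a control parameter, one simulation per grid value
#'
#' Runs one independent [grn_simulate()] per value of the control parameter,
#' with child seeds derived deterministically from the base seed and grid
#' index.
#'
#' @param params A [grn_network()] parameter object.
#' @param control `"m1"`, `"m2"`, or `"k_d"`.
#' @param grid Sorted numeric vector of control values.
#' @param seed Base seed; defaults to `params$seed`.
#' @return A tibble of class `grn_sweep` with columns `control_value` and
#'   `matrix` (list of [expr_matrix()]); the control name is kept as an
#'   attribute.
#' @export
grn_sweep <- function(params, control = c("m1", "m2", "k_d"), grid, seed = NULL) {
  control <- match.arg(control)
  if (is.unsorted(grid)) {
    abort("`grid` must be sorted increasing.", class = "bifurscan_config_error")
  }
  seed <- seed %||% params$seed
  out <- purrr::imap(grid, function(value, i) {
    p <- params
    p[[control]] <- value
    tibble(control_value = value,
           matrix = list(grn_simulate(p, seed = derive_seed(seed, i))))
  })
  out <- bind_rows(out)
  attr(out, "control") <- control
  attr(out, "params") <- params
  class(out) <- c("grn_sweep", class(out))
  out
}

#' Stack a sweep into one expression matrix with the control as pseudotime
#'
#' Concatenates the per-grid-value matrices of a [grn_sweep()] in control
#' order, assigning each cell the control value as its pseudotime. Useful
#' for running the trajectory scan with the control parameter playing the
#' role of pseudotime.
#'
#' @param sweep A `grn_sweep` result.
#' @return An [expr_matrix()] with pseudotime set.
#' @export
sweep_to_matrix <- function(sweep) {
  mats <- purrr::map2(sweep$matrix, seq_len(nrow(sweep)), function(m, i) {
    rownames(m) <- paste0("v", i, "_", rownames(m))
    m
  })
  values <- do.call(rbind, purrr::map(mats, unclass_expr))
  pt <- rep(sweep$control_value, vapply(sweep$matrix, nrow, integer(1)))
  expr_matrix(values, pseudotime = pt)
}
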