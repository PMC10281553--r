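#' Build a two-driver toggle-switch gene regulatory network
#'
#' Constructs the parameterization of a stochastic network in which two
#' mutually inhibiting "driver" genes (`g1`, `g2`) generate multistability,
#' and each of the remaining `n_genes - 2` "responder" genes is coupled to
#' exactly one driver with strength `alpha` in \[0, 1\] (`alpha = 0`: full
#' inhibition, `alpha = 1`: full activation). Driver assignment is balanced
#' (half the responders per driver) and deterministic; coupling strengths are
#' drawn from the chosen sampler under `seed`, so the same call always
#' produces the same network.
#'
#' @param n_genes Total gene count (drivers + responders), at least 2.
#'   Default 102 (two drivers + 100 responders).
#' @param n_cells Number of cells (independent statistical replicates)
#'   simulated per run. Default 100.
#' @param m1,m2 Driver synthesis scales (dimensionless rates).
#' @param k_d Driver degradation rate.
#' @param k_resp Responder degradation rate(s); recycled to the number of
#'   responders. Default 1.
#' @param noise Noise scale `1/s` of the simulation; the per-gene Gaussian
#'   increment has variance `dt * (synthesis + degradation) / s`. Default
#'   0.05. Use 0 for deterministic integration.
#' @param dt Euler timestep. Default 0.01.
#' @param n_steps Number of integration steps. Default 2e4 (about 200 time
#'   units, two orders of magnitude beyond the ~1 time-unit relaxation scale).
#' @param init_range Interval from which initial expression is drawn
#'   uniformly, default `c(0, 4)`.
#' @param alpha_sampling `"uniform"` (default) draws responder couplings
#'   uniformly on \[0, 1\]; `"grid"` spaces them evenly on \[0, 1\] per
#'   driver; a single number in \[0, 1\] fixes all couplings to that value.
#' @param seed Integer RNG seed used for coupling draws and as the base seed
#'   for simulation.
#'
#' @return An object of class `grn_params`: a list with the driver
#'   parameters, per-responder `alpha`, `driver_of`, `k_resp`, and the
#'   simulation settings. `tidy()` returns the per-gene table, `glance()`
#'   the scalar settings.
#' @export
#' @examples
#' net <- grn_network(n_genes = 10, seed = 1)
#' tidy(net)
grn_network <- function(n_genes = 102, n_cells = 100, m1 = 3, m2 = 3, k_d = 1,
                        k_resp = 1, noise = 0.05, dt = 0.01, n_steps = 2e4,
                        init_range = c(0, 4), alpha_sampling = "uniform",
                        seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 2) {
    abort("`n_genes` must be at least 2 (the two drivers).",
          class = "bifurscan_invalid_network")
  }
  n_genes <- as.integer(n_genes)
  n_cells <- as.integer(n_cells)
  if (n_cells < 2) abort("`n_cells` must be at least 2.", class = "bifurscan_invalid_network")
  for (nm in c("m1", "m2", "k_d")) stopifnot_scalar_number(get(nm), nm, positive = TRUE)
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  stopifnot_scalar_number(noise, "noise")
  if (noise < 0) abort("`noise` must be nonnegative.", class = "bifurscan_config_error")
  if (length(init_range) != 2L || any(init_range < 0) || diff(init_range) < 0) {
    abort("`init_range` must be a nonnegative, nondecreasing interval.",
          class = "bifurscan_config_error")
  }
  n_resp <- n_genes - 2L
  k_resp <- rep_len(as.numeric(k_resp), max(n_resp, 1L))[seq_len(n_resp)]
  if (n_resp > 0 && any(k_resp <= 0)) {
    abort("Responder degradation rates must be positive.",
          class = "bifurscan_invalid_network")
  }
  # balanced driver assignment, deterministic: alternate 1, 2, 1, 2, ...
  driver_of <- rep_len(c(1L, 2L), n_resp)
  alpha <- if (n_resp == 0L) {
    numeric(0)
  } else if (is.numeric(alpha_sampling)) {
    if (alpha_sampling < 0 || alpha_sampling > 1) {
      abort("Constant `alpha_sampling` must lie in [0, 1].",
            class = "bifurscan_config_error")
    }
    rep(as.numeric(alpha_sampling), n_resp)
  } else if (identical(alpha_sampling, "uniform")) {
    with_seed(seed, runif(n_resp))
  } else if (identical(alpha_sampling, "grid")) {
    stats::ave(numeric(n_resp), driver_of,
               FUN = function(z) seq(0, 1, length.out = length(z)))
  } else {
    abort("`alpha_sampling` must be \"uniform\", \"grid\", or a number in [0, 1].",
          class = "bifurscan_config_error")
  }
  structure(
    list(
      n_genes = n_genes, n_cells = n_cells,
      m1 = m1, m2 = m2, k_d = k_d, k_resp = k_resp,
      alpha = alpha, driver_of = driver_of,
      noise = noise, dt = dt, n_steps = as.integer(n_steps),
      init_range = as.numeric(init_range), seed = as.integer(seed),
      gene_names = c("g1", "g2", if (n_resp > 0) paste0("r", seq_len(n_resp)))
    ),
    class = "grn_params"
  )
}

#' @export
print.grn_params <- function(x, ...) {
  cat(sprintf("<grn_params> %d genes (2 drivers + %d responders), %d cells\n",
              x$n_genes, x$n_genes - 2L, x$n_cells))
  cat(sprintf("  m1 = %g, m2 = %g, k_d = %g, noise 1/s = %g\n", x$m1, x$m2, x$k_d, x$noise))
  cat(sprintf("  dt = %g, n_steps = %d, seed = %d\n", x$dt, x$n_steps, x$seed))
  invisible(x)
}

#' @describeIn grn_network Per-gene tibble: gene, role, driver, alpha,
#'   degradation and synthesis scale.
#' @param x A `grn_params` object.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.grn_params <- function(x, ...) {
  n_resp <- x$n_genes - 2L
  tibble(
    gene = x$gene_names,
    role = c("driver", "driver", rep("responder", n_resp)),
    driver = c(NA_integer_, NA_integer_, x$driver_of),
    alpha = c(NA_real_, NA_real_, x$alpha),
    degradation = c(x$k_d, x$k_d, x$k_resp),
    synthesis_scale = c(x$m1, x$m2, c(x$m1, x$m2)[x$driver_of])
  )
}

#' @describeIn grn_network One-row tibble of scalar network settings.
#' @export
#' @exportS3Method generics::glance
glance.grn_params <- function(x, ...) {
  tibble(
    n_genes = x$n_genes, n_cells = x$n_cells, m1 = x$m1, m2 = x$m2,
    k_d = x$k_d, noise = x$noise, dt = x$dt, n_steps = x$n_steps,
    seed = x$seed
  )
}
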