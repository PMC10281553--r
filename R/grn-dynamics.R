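#' Deterministic drift of the toggle-switch network
#'
#' Right-hand side of the network ODEs. The drivers mutually inhibit through
#' Hill-2 repression, `dg1/dt = -k_d g1 + m1 / (1 + g2^2)` (and symmetrically
#' for `g2`); each responder relaxes at rate `k_i` toward an
#' `alpha`-interpolated mixture of activating and inhibiting Hill-2 terms in
#' its driver's expression,
#' `dg_i/dt = -k_i g_i + m_d (alpha_i g_d^2 + (1 - alpha_i)) / (1 + g_d^2)`.
#'
#' @param state Nonnegative numeric vector of length `n_genes`.
#' @param params A [grn_network()] parameter object.
#' @return Numeric vector of per-gene time derivatives.
#' @export
#' @examples
#' net <- grn_network(n_genes = 4, m1 = 1, m2 = 1, k_d = 0.5, seed = 1)
#' grn_drift(c(1, 1, 0.5, 0.5), net)
grn_drift <- function(state, params) {
  check_state(state, params)
  grn_synthesis(state, params) - grn_degradation(state, params)
}

# Per-gene synthesis rates (always nonnegative); shared with the noise model.
grn_synthesis <- function(state, params) {
  g1 <- state[1L]; g2 <- state[2L]
  syn <- c(params$m1 / (1 + g2^2), params$m2 / (1 + g1^2))
  n_resp <- params$n_genes - 2L
  if (n_resp > 0L) {
    gd <- state[params$driver_of]
    m_d <- c(params$m1, params$m2)[params$driver_of]
    syn <- c(syn, m_d * (params$alpha * gd^2 + (1 - params$alpha)) / (1 + gd^2))
  }
  unname(syn)
}

grn_degradation <- function(state, params) {
  unname(c(params$k_d, params$k_d, params$k_resp) * state)
}

check_state <- function(state, params) {
  if (length(state) != params$n_genes) {
    abort(sprintf("`state` must have length n_genes = %d.", params$n_genes),
          class = "bifurscan_domain_error")
  }
  if (any(state < 0) || any(!is.finite(state))) {
    abort("`state` entries must be finite and nonnegative.",
          class = "bifurscan_domain_error")
  }
  invisible(state)
}

#' Jacobian of the network drift
#'
#' Analytic partial derivatives of [grn_drift()]. Diagonal entries are the
#' negated degradation rates; the driver block couples through
#' `d f1 / d g2 = -2 m1 g2 / (1 + g2^2)^2`; each responder row has a single
#' off-diagonal entry in its driver's column,
#' `m_d (2 alpha_i - 1) 2 g_d / (1 + g_d^2)^2`.
#'
#' @inheritParams grn_drift
#' @return Dense `n_genes` x `n_genes` numeric matrix.
#' @seealso [slowest_mode()] for the leading eigenvalue/eigenvector.
#' @export
grn_jacobian <- function(state, params) {
  check_state(state, params)
  n <- params$n_genes
  J <- matrix(0, n, n, dimnames = list(params$gene_names, params$gene_names))
  g1 <- state[1L]; g2 <- state[2L]
  diag(J) <- -c(params$k_d, params$k_d, params$k_resp)
  J[1L, 2L] <- -2 * params$m1 * g2 / (1 + g2^2)^2
  J[2L, 1L] <- -2 * params$m2 * g1 / (1 + g1^2)^2
  if (n > 2L) {
    gd <- state[params$driver_of]
    m_d <- c(params$m1, params$m2)[params$driver_of]
    dsyn <- m_d * (2 * params$alpha - 1) * 2 * gd / (1 + gd^2)^2
    J[cbind(seq.int(3L, n), params$driver_of)] <- dsyn
  }
  J
}

#' Leading (slowest) eigenmode of a Jacobian
#'
#' Largest-real-part eigenvalue and its right eigenvector, sign-fixed so the
#' largest-magnitude component is positive. Near a bifurcation this
#' eigenvalue approaches zero from below and the eigenvector is the
#' direction along which stability is lost.
#'
#' @param J Square numeric matrix.
#' @return List with `lambda` (real part of the leading eigenvalue) and
#'   `vector` (unit-norm real eigenvector).
#' @export
slowest_mode <- function(J) {
  e <- eigen(J)
  i <- which.max(Re(e$values))
  v <- e$vectors[, i]
  if (max(abs(Im(v))) > 1e-8 * max(abs(v))) {
    warn("Leading eigenvector has a nontrivial imaginary part; using its real part.")
  }
  v <- Re(v)
  v <- v / sqrt(sum(v^2))
  list(lambda = Re(e$values[i]), vector = fix_sign(v))
}

#' Fixed points of the driver core
#'
#' Enumerates the fixed points of the two-dimensional mutual-inhibition
#' driver core by reducing to one dimension (`g2* = m2 / (k_d (1 + g1*^2))`)
#' and bracketing all sign changes of the remaining residual on a fine grid,
#' then refining by bisection. Responder steady states follow in closed form
#' from the driver values. Each point is labeled stable/unstable by the sign
#' of the largest driver-core Jacobian eigenvalue.
#'
#' @param params A [grn_network()] parameter object.
#' @param grid_n Number of grid points used to bracket roots. Default 2000.
#' @param tol Root tolerance. Default 1e-10.
#' @return A tibble with one row per fixed point: `g1`, `g2`, `lambda_d`
#'   (largest driver-core eigenvalue), `stable`, `drift_norm`, and a
#'   list-column `state` holding the full named steady state.
#' @export
#' @examples
#' grn_fixed_points(grn_network(n_genes = 2, m1 = 3, m2 = 3, k_d = 1))
grn_fixed_points <- function(params, grid_n = 2000L, tol = 1e-12) {
  m1 <- params$m1; m2 <- params$m2; kd <- params$k_d
  g2_of <- function(g1) m2 / (kd * (1 + g1^2))
  resid <- function(g1) -kd * g1 + m1 / (1 + g2_of(g1)^2)
  g_max <- max(m1, m2) / kd + 1
  grid <- seq(0, g_max, length.out = grid_n)
  r <- vapply(grid, resid, numeric(1))
  roots <- numeric(0)
  sign_change <- which(r[-1] * r[-length(r)] <= 0)
  for (i in sign_change) {
    if (r[i] == 0) { roots <- c(roots, grid[i]); next }
    roots <- c(roots, uniroot(resid, c(grid[i], grid[i + 1]), tol = tol)$root)
  }
  roots <- sort(unique(roots))
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) > 1e-6)
    roots <- roots[keep]
  }
  if (length(roots) == 0L) {
    abort("Fixed-point search failed: no root bracketed on the grid.",
          class = "bifurscan_solver_error")
  }
  rows <- purrr::map(roots, function(g1) {
    g2 <- g2_of(g1)
    state <- driver_to_state(g1, g2, params)
    lam <- driver_core_lambda(g1, g2, params)
    dn <- max(abs(grn_drift(state, params)))
    tibble(g1 = g1, g2 = g2, lambda_d = lam, stable = lam < 0,
           drift_norm = dn, state = list(state))
  })
  out <- bind_rows(rows)
  bad <- out$drift_norm > 1e-6
  if (any(bad)) {
    abort("Fixed-point refinement did not converge (drift norm above tolerance).",
          class = "bifurscan_solver_error")
  }
  out
}

# Full steady state given driver values: responders in closed form.
driver_to_state <- function(g1, g2, params) {
  state <- c(g1, g2)
  n_resp <- params$n_genes - 2L
  if (n_resp > 0L) {
    gd <- c(g1, g2)[params$driver_of]
    m_d <- c(params$m1, params$m2)[params$driver_of]
    state <- c(state,
               m_d * (params$alpha * gd^2 + (1 - params$alpha)) /
                 ((1 + gd^2) * params$k_resp))
  }
  setNames(state, params$gene_names)
}

# Largest eigenvalue of the 2x2 driver-core Jacobian.
driver_core_lambda <- function(g1, g2, params) {
  a12 <- -2 * params$m1 * g2 / (1 + g2^2)^2
  a21 <- -2 * params$m2 * g1 / (1 + g1^2)^2
  max(Re(eigen(matrix(c(-params$k_d, a21, a12, -params$k_d), 2, 2),
               only.values = TRUE)$values))
}

#' Critical value of a control parameter
#'
#' Locates the control-parameter value at which the tracked fixed point of
#' the driver core changes character, by bisection over `bracket`.
#'
#' Two criteria are available. `"eigenvalue"` bisects on the largest
#' driver-core Jacobian eigenvalue of the tracked fixed point (the point
#' closest to symmetric, which for `m1 == m2` is the exactly symmetric one)
#' and returns the value where linear stability is lost; this locates the
#' pitchfork at `k_d = 0.5` for `m1 = m2 = 1`. `"balance"` bisects on the
#' asymmetry `g1* - g2*` of the near-symmetric fixed point and returns the
#' value at which the bistable double well is balanced; for a saddle-node
#' pair this is where the steady-state distribution is symmetric and
#' bimodal (`m1 = 3` for `m2 = 3`, `k_d = 1`). For `"balance"` the bracket
#' must lie inside the multistable window so that the tracked asymmetry is
#' continuous.
#'
#' @param params A [grn_network()] parameter object; the tracked value of
#'   the control in `params` is ignored.
#' @param control `"k_d"` or `"m1"`.
#' @param bracket Length-2 numeric interval to search.
#' @param criterion `"eigenvalue"` (default for `"k_d"`) or `"balance"`
#'   (default for `"m1"`).
#' @param tol Bisection stops when the tracked indicator is within `tol` of
#'   zero. Default 1e-8.
#' @param max_iter Iteration cap. Default 200.
#' @return An object of class `grn_critical`: list with `control`,
#'   `critical_value`, `criterion`, `iterations`, and a `trace` tibble of
#'   (control value, indicator) pairs visited.
#' @export
#' @examples
#' net <- grn_network(n_genes = 2, m1 = 1, m2 = 1)
#' grn_critical(net, "k_d", c(0.24, 5))$critical_value  # 0.5
grn_critical <- function(params, control = c("k_d", "m1"),
                         bracket, criterion = NULL, tol = 1e-8,
                         max_iter = 200L) {
  control <- match.arg(control)
  criterion <- criterion %||% if (control == "k_d") "eigenvalue" else "balance"
  if (!criterion %in% c("eigenvalue", "balance")) {
    abort("`criterion` must be \"eigenvalue\" or \"balance\".",
          class = "bifurscan_config_error")
  }
  if (length(bracket) != 2L || diff(bracket) <= 0) {
    abort("`bracket` must be an increasing interval.", class = "bifurscan_config_error")
  }
  stopifnot_scalar_number(tol, "tol", positive = TRUE)

  indicator <- function(value) {
    p <- params
    p[[control]] <- value
    if (criterion == "eigenvalue" && p$m1 == p$m2) {
      # the symmetric point solves k_d g (1 + g^2) = m exactly; tracking it
      # through a 1-D monotone root keeps the eigenvalue smooth through the
      # pitchfork, where the full enumeration has three nearby roots
      g <- uniroot(function(g) p$k_d * g * (1 + g^2) - p$m1,
                   c(0, p$m1 / p$k_d + 1), tol = 1e-14)$root
      return(-p$k_d + 2 * p$m1 * g / (1 + g^2)^2)
    }
    fp <- grn_fixed_points(p)
    tracked <- fp[which.min(abs(fp$g1 - fp$g2)), ]
    if (criterion == "eigenvalue") tracked$lambda_d else tracked$g1 - tracked$g2
  }

  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- indicator(lo); f_hi <- indicator(hi)
  trace <- tibble(value = c(lo, hi), indicator = c(f_lo, f_hi))
  if (sign(f_lo) == sign(f_hi)) {
    abort(sprintf(
      "No sign change of the %s indicator in [%g, %g] (values %.4g and %.4g).",
      criterion, lo, hi, f_lo, f_hi), class = "bifurscan_bracket_error")
  }
  it <- 0L; mid <- (lo + hi) / 2
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    f_mid <- indicator(mid)
    trace <- bind_rows(trace, tibble(value = mid, indicator = f_mid))
    if (abs(f_mid) < tol || mid <= lo || mid >= hi || it >= max_iter) break
    if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid } else { hi <- mid }
  }
  structure(
    list(control = control, critical_value = mid, criterion = criterion,
         iterations = it, trace = trace),
    class = "grn_critical"
  )
}

#' @export
print.grn_critical <- function(x, ...) {
  cat(sprintf("<grn_critical> %s criterion: %s = %.8g (%d bisection steps)\n",
              x$criterion, x$control, x$critical_value, x$iterations))
  invisible(x)
}
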