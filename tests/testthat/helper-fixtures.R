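# Shared fixtures, computed lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Compact saddle-node network: 30 genes, short equilibration. Used by the
# unit tests; the acceptance tests run the full-size study conditions.
small_net <- function() {
  grn_network(n_genes = 30, n_cells = 100, m2 = 3, k_d = 1,
              n_steps = 4000, seed = 42)
}

small_sweep <- function() {
  cached("small_sweep", grn_sweep(small_net(), "m1", c(2, 2.5, 3, 3.5, 4)))
}

# Full study-condition sweep (102 genes, 100 cells, 2e4 steps, m1 grid
# 2..4 by 0.25 at k_d = 1, m2 = 3, 1/s = 0.05).
acceptance_net <- function() grn_network(n_genes = 102, n_cells = 100, seed = 101)

acceptance_sweep <- function() {
  cached("acceptance_sweep",
         grn_sweep(acceptance_net(), "m1", seq(2, 4, by = 0.25)))
}

# Random stable system + independent vectorized Lyapunov oracle.
random_stable_system <- function(n) {
  J <- matrix(rnorm(n * n), n, n) - (n + 2) * diag(n)
  A <- matrix(rnorm(n * n), n, n)
  list(J = J, Q = crossprod(A))
}

lyapunov_oracle <- function(J, Q) {
  n <- nrow(J)
  matrix(solve(diag(n) %x% J + J %x% diag(n), -as.vector(Q)), n, n)
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
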