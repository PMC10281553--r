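#' Solve the continuous-time Lyapunov equation
#'
#' Solves `J C + C J' + Q = 0` for the stationary covariance `C` of the
#' Ornstein–Uhlenbeck process `dx = J x dt + noise`, where `J` is stable
#' (Hurwitz) and `Q` is the symmetric positive-semidefinite noise
#' covariance intensity. Uses the Bartels–Stewart approach: a real Schur
#' factorization of `J` followed by blockwise back-substitution in the
#' quasi-triangular basis, which remains well conditioned even when
#' eigenvalues nearly coincide (as they do near the network's pitchfork,
#' where the fast driver mode collides with the responder relaxation rates).
#'
#' @param J Square numeric matrix with all eigenvalues in the open left
#'   half-plane.
#' @param Q Symmetric positive-semidefinite matrix of the same dimension.
#' @return An object of class `lyapunov_solution`: list with `C` (symmetric
#'   PSD), `residual` (Frobenius norm of `J C + C J' + Q`) and
#'   `residual_rel` (relative to `||Q||_F`).
#' @export
#' @examples
#' s <- solve_lyapunov(-diag(2), 2 * diag(2))
#' s$C  # identity
solve_lyapunov <- function(J, Q) {
  if (!is.matrix(J) || nrow(J) != ncol(J)) {
    abort("`J` must be a square matrix.", class = "bifurscan_shape_error")
  }
  if (!is.matrix(Q) || any(dim(Q) != dim(J))) {
    abort("`Q` must be a square matrix of the same dimension as `J`.",
          class = "bifurscan_shape_error")
  }
  if (max(abs(Q - t(Q))) > 1e-8 * max(1, max(abs(Q)))) {
    abort("`Q` must be symmetric.", class = "bifurscan_shape_error")
  }
  ev <- eigen(J, only.values = TRUE)$values
  if (max(Re(ev)) >= 0) {
    abort(sprintf("`J` is not Hurwitz: largest real part %.4g >= 0.", max(Re(ev))),
          class = "bifurscan_stability_error")
  }
  n <- nrow(J)
  sch <- Matrix::Schur(Matrix::Matrix(J, sparse = FALSE))
  U <- as.matrix(sch@Q)   # orthogonal
  S <- as.matrix(sch@T)   # quasi upper triangular
  F_ <- crossprod(U, Q %*% U)  # U' Q U

  # block partition of S: 2x2 blocks where the subdiagonal is nonzero
  starts <- integer(0)
  i <- 1L
  while (i <= n) {
    starts <- c(starts, i)
    if (i < n && abs(S[i + 1L, i]) > .Machine$double.eps * 100 * max(abs(diag(S)), 1)) {
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  blocks <- purrr::map2(starts, c(starts[-1L] - 1L, n), seq.int)

  Y <- matrix(0, n, n)
  for (kb in rev(seq_along(blocks))) {
    K <- blocks[[kb]]
    rhs <- -F_[, K, drop = FALSE]
    if (kb < length(blocks)) {
      Jidx <- unlist(blocks[(kb + 1L):length(blocks)])
      rhs <- rhs - Y[, Jidx, drop = FALSE] %*% t(S[K, Jidx, drop = FALSE])
    }
    b <- length(K)
    if (b == 1L) {
      Y[, K] <- solve(S + S[K, K] * diag(n), rhs)
    } else {
      M <- diag(b) %x% S + S[K, K, drop = FALSE] %x% diag(n)
      Y[, K] <- matrix(solve(M, as.vector(rhs)), n, b)
    }
  }
  C <- U %*% Y %*% t(U)
  C <- (C + t(C)) / 2
  res <- J %*% C + C %*% t(J) + Q
  residual <- sqrt(sum(res^2))
  structure(
    list(C = C, residual = residual,
         residual_rel = residual / max(sqrt(sum(Q^2)), .Machine$double.eps)),
    class = "lyapunov_solution"
  )
}

#' @export
print.lyapunov_solution <- function(x, ...) {
  cat(sprintf("<lyapunov_solution> %d x %d, residual %.3g (rel %.3g)\n",
              nrow(x$C), ncol(x$C), x$residual, x$residual_rel))
  invisible(x)
}

#' @describeIn solve_lyapunov One-row tibble: dimension, top covariance
#'   eigenvalue, residuals.
#' @param x A `lyapunov_solution`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::glance
glance.lyapunov_solution <- function(x, ...) {
  tibble(dim = nrow(x$C),
         omega1 = max(eigen(x$C, symmetric = TRUE, only.values = TRUE)$values),
         residual = x$residual, residual_rel = x$residual_rel)
}

#' Diagonal noise covariance intensity of the network at a state
#'
#' The simulator draws per-gene Gaussian increments with variance
#' `dt * (synthesis + degradation) * noise`, independently per gene; the
#' corresponding continuous-time noise intensity entering the Lyapunov
#' equation is the diagonal matrix `(synthesis + degradation) * noise`.
#'
#' @inheritParams grn_drift
#' @return Diagonal `n_genes` x `n_genes` matrix.
#' @export
grn_noise_covariance <- function(state, params) {
  check_state(state, params)
  q <- (grn_synthesis(state, params) + grn_degradation(state, params)) * params$noise
  diag(q, nrow = params$n_genes)
}

#' Lyapunov-predicted covariance eigenstructure along a control scan
#'
#' For each control value: locates the tracked (near-symmetric, stable)
#' fixed point, assembles the full-network Jacobian and diagonal noise
#' intensity there, solves the Lyapunov equation, and compares the principal
#' covariance eigenvector with the Jacobian's slowest eigenvector. As the
#' leading Jacobian eigenvalue approaches zero the principal covariance
#' eigenvalue diverges and the two directions coincide up to sign.
#'
#' @param params A [grn_network()] parameter object.
#' @param control `"k_d"`, `"m1"`, or `"m2"`.
#' @param values Control values to scan.
#' @return Tibble: `control_value`, `lambda_d` (leading Jacobian
#'   eigenvalue), `omega1` (principal covariance eigenvalue of the Lyapunov
#'   solution), `distance` (sign-aligned Euclidean distance between the two
#'   principal directions).
#' @export
stability_scan <- function(params, control = c("k_d", "m1", "m2"), values) {
  control <- match.arg(control)
  rows <- purrr::map(values, function(v) {
    p <- params
    p[[control]] <- v
    fp <- grn_fixed_points(p)
    fp <- fp[fp$stable, , drop = FALSE]
    if (nrow(fp) == 0L) {
      abort(sprintf("No stable fixed point at %s = %g.", control, v),
            class = "bifurscan_stability_error")
    }
    fp <- fp[which.min(abs(fp$g1 - fp$g2)), ]
    state <- fp$state[[1L]]
    J <- grn_jacobian(state, p)
    mode <- slowest_mode(J)
    sol <- solve_lyapunov(J, grn_noise_covariance(state, p))
    ce <- eigen(sol$C, symmetric = TRUE)
    tibble(control_value = v, lambda_d = mode$lambda,
           omega1 = ce$values[1L],
           distance = eigvec_alignment(ce$vectors[, 1L], mode$vector))
  })
  bind_rows(rows)
}
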