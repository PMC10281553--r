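# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic child seed; kept well below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) + 1009 * as.double(index)) %% 2147483629)
}

# Fix the sign of an eigen/singular vector: largest-magnitude component positive.
# Ties resolved by the first occurrence.
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name), class = "bifurscan_config_error")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name), class = "bifurscan_config_error")
  }
  invisible(x)
}
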