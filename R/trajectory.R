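#' Row (cell) normalization
#'
#' Scales each cell's expression vector. `"unit-sum"` (default) divides by
#' the row total so rows sum to 1 (total-count normalization);
#' `"median-count"` scales rows to the median row total; `"none"` returns
#' the input unchanged.
#'
#' @inheritParams covariance_eig
#' @param method Normalization mode.
#' @return Matrix of the same shape (an [expr_matrix()] if the input was
#'   one, with pseudotime preserved).
#' @export
#' @examples
#' normalize_cells(matrix(c(1, 1, 2), 1, 3))  # 0.25 0.25 0.5
normalize_cells <- function(x, method = c("unit-sum", "median-count", "none")) {
  method <- match.arg(method)
  m <- as_expr_values(x)
  if (method == "none") return(restore_expr(m, x))
  totals <- rowSums(m)
  zero <- totals <= 0
  if (any(zero)) {
    abort(sprintf("Cells with zero total expression cannot be normalized: %s",
                  paste(rownames(m)[zero], collapse = ", ")),
          class = "bifurscan_zero_row_error")
  }
  scale_to <- if (method == "unit-sum") 1 else median(totals)
  restore_expr(m * (scale_to / totals), x)
}

restore_expr <- function(m, original) {
  if (inherits(original, "expr_matrix")) {
    expr_matrix(m, pseudotime = pseudotime(original))
  } else {
    m
  }
}

#' Overlapping bins along pseudotime
#'
#' Sorts cells by pseudotime (ties broken by stable input order) and forms
#' bins of `bin_size` consecutive cells starting every
#' `step = round(bin_size * (1 - overlap))` cells, for every offset with
#' `offset + bin_size <= n_cells`; the final bin absorbs any trailing cells,
#' so its size lies in `[bin_size, bin_size + step)`. Bin labels are
#' 1-based.
#'
#' @param pt Numeric pseudotime vector (one value per cell), or a single
#'   integer giving the number of already-ranked cells.
#' @param bin_size Cells per bin.
#' @param overlap Fraction of overlap between neighboring bins, in `[0, 1)`.
#'   Default 0.5.
#' @return A tibble of class `binned_trajectory`: `bin`, `cells` (list of
#'   original cell indices, pseudotime order), `n_cells`,
#'   `mean_pseudotime`.
#' @export
#' @examples
#' bin_by_pseudotime(2500, bin_size = 1000)  # 4 bins at offsets 0,500,1000,1500
bin_by_pseudotime <- function(pt, bin_size, overlap = 0.5) {
  if (length(pt) == 1L && is.numeric(pt)) pt <- seq_len(pt)
  n <- length(pt)
  bin_size <- as.integer(bin_size)
  if (n < bin_size) {
    abort(sprintf("n_cells = %d is smaller than bin_size = %d; use a smaller bin.",
                  n, bin_size), class = "bifurscan_binning_error")
  }
  if (overlap < 0 || overlap >= 1) {
    abort("`overlap` must lie in [0, 1).", class = "bifurscan_config_error")
  }
  ord <- order(pt)  # stable for ties
  step <- max(1L, as.integer(round(bin_size * (1 - overlap))))
  offsets <- seq.int(0L, n - bin_size, by = step)
  n_bins <- length(offsets)
  rows <- purrr::imap(offsets, function(off, b) {
    last <- if (b == n_bins) n else off + bin_size
    idx <- ord[(off + 1L):last]
    tibble(bin = b, cells = list(idx), n_cells = length(idx),
           mean_pseudotime = mean(pt[idx]))
  })
  out <- bind_rows(rows)
  attr(out, "bin_size") <- bin_size
  attr(out, "overlap") <- overlap
  class(out) <- c("binned_trajectory", class(out))
  out
}

#' Principal covariance eigenvalue per pseudotime bin
#'
#' Computes [covariance_eig()] on each bin's submatrix and returns the
#' per-bin `omega1` trajectory together with its min-shifted version.
#'
#' @inheritParams covariance_eig
#' @param bins A [bin_by_pseudotime()] result over the same cells.
#' @return Tibble: `bin`, `n_cells`, `mean_pseudotime`, `omega1`,
#'   `omega1_shifted` (minimum exactly 0).
#' @export
omega_trajectory <- function(x, bins) {
  m <- as_expr_values(x)
  check_bins(bins, nrow(m))
  out <- mutate(
    select(bins, "bin", "n_cells", "mean_pseudotime"),
    omega1 = map_dbl(bins$cells, function(idx) {
      covariance_eig(m[idx, , drop = FALSE], k = 1L)$values[1L]
    })
  )
  mutate(out, omega1_shifted = .data$omega1 - min(.data$omega1))
}

check_bins <- function(bins, n_cells) {
  if (!inherits(bins, "binned_trajectory")) {
    abort("`bins` must come from bin_by_pseudotime().", class = "bifurscan_config_error")
  }
  idx <- unlist(bins$cells)
  if (max(idx) > n_cells) {
    abort("Bin cell indices exceed the number of cells in the matrix.",
          class = "bifurscan_shape_error")
  }
  if (any(bins$n_cells < 2L)) {
    abort("Every bin must contain at least 2 cells.", class = "bifurscan_binning_error")
  }
  invisible(bins)
}

#' Gene-shuffled null for the eigenvalue trajectory
#'
#' For each bin and replicate, every gene column is permuted independently
#' across the bin's cells: per-gene marginals (mean, variance) are preserved
#' exactly while gene-gene correlations are destroyed. Returns the per-bin
#' mean and standard deviation of the null `omega1`.
#'
#' @inheritParams omega_trajectory
#' @param n_reps Number of null replicates per bin (at least 2). Default 20.
#' @param seed RNG seed.
#' @return Tibble: `bin`, `null_mean`, `null_sd`.
#' @export
null_trajectory <- function(x, bins, n_reps = 20L, seed = 1L) {
  if (n_reps < 2L) {
    abort("`n_reps` must be at least 2.", class = "bifurscan_config_error")
  }
  m <- as_expr_values(x)
  check_bins(bins, nrow(m))
  with_seed(seed, {
    stats <- purrr::map(bins$cells, function(idx) {
      sub <- m[idx, , drop = FALSE]
      n <- nrow(sub)
      om <- vapply(seq_len(n_reps), function(r) {
        perm <- apply(sub, 2L, function(col) col[sample.int(n)])
        covariance_eig(perm, k = 1L)$values[1L]
      }, numeric(1))
      c(mean(om), sd(om))
    })
  })
  tibble(bin = bins$bin,
         null_mean = map_dbl(stats, 1L),
         null_sd = map_dbl(stats, 2L))
}

#' Dynamical network biomarker (DNB) order parameter
#'
#' Composite index
#' `I = SD_avg(DNB) * |PCC|_avg(within DNB) / (|PCC|_avg(DNB vs rest) + eps)`:
#' the average standard deviation of the biomarker genes, times their
#' average absolute within-group Pearson correlation, divided by their
#' average absolute correlation with all other genes. The index rises near
#' a critical transition when the biomarker group fluctuates strongly and
#' coherently while decoupling from the rest.
#'
#' @inheritParams covariance_eig
#' @param dnb_genes Character vector of biomarker gene names; must be a
#'   nonempty proper subset of the matrix genes.
#' @param eps Guard added to the denominator. Default 1e-6.
#' @return Scalar index value.
#' @export
dnb_order_parameter <- function(x, dnb_genes, eps = 1e-6) {
  m <- as_expr_values(x)
  genes <- colnames(m)
  if (length(dnb_genes) == 0L) {
    abort("`dnb_genes` must be nonempty.", class = "bifurscan_set_error")
  }
  missing <- setdiff(dnb_genes, genes)
  if (length(missing) > 0L) {
    abort(sprintf("DNB genes absent from the matrix: %s",
                  paste(missing, collapse = ", ")), class = "bifurscan_set_error")
  }
  rest <- setdiff(genes, dnb_genes)
  if (length(rest) == 0L) {
    abort("`dnb_genes` must be a proper subset of the matrix genes.",
          class = "bifurscan_set_error")
  }
  R <- suppressWarnings(cor(m))
  in_idx <- match(dnb_genes, genes)
  out_idx <- match(rest, genes)
  sd_avg <- mean(apply(m[, in_idx, drop = FALSE], 2L, sd))
  within <- abs(R[in_idx, in_idx])[upper.tri(diag(length(in_idx)))]
  cross <- abs(R[in_idx, out_idx, drop = FALSE])
  pcc_in <- if (length(within) == 0L) 1 else mean(within, na.rm = TRUE)
  pcc_cross <- mean(cross, na.rm = TRUE)
  if (!is.finite(pcc_in)) pcc_in <- 0
  if (!is.finite(pcc_cross)) pcc_cross <- 0
  sd_avg * pcc_in / (pcc_cross + eps)
}

#' Scan a trajectory for bifurcation signatures
#'
#' The full analysis pipeline: normalize cells, bin along pseudotime,
#' compute the per-bin principal covariance eigenvalue, compare with the
#' gene-shuffled null, and optionally track a DNB gene set. The returned
#' table carries the per-bin z-score
#' `z = (omega1 - null_mean) / null_sd`; both the data and null curves are
#' also reported min-shifted to zero.
#'
#' @inheritParams covariance_eig
#' @param pt Pseudotime per cell; defaults to the matrix's stored
#'   pseudotime.
#' @param bin_size,overlap Binning parameters (see [bin_by_pseudotime()]).
#' @param normalize Cell normalization mode (see [normalize_cells()]).
#' @param n_reps Null replicates per bin. Default 20.
#' @param seed RNG seed for the null.
#' @param dnb_genes Optional DNB gene set; adds a `dnb` column.
#' @return A tibble of class `omega_scan`: `bin`, `n_cells`,
#'   `mean_pseudotime`, `omega1`, `omega1_shifted`, `null_mean`,
#'   `null_mean_shifted`, `null_sd`, `z`, and optionally `dnb`. The binning
#'   is kept as attribute `"bins"`.
#' @export
scan_trajectory <- function(x, pt = NULL, bin_size, overlap = 0.5,
                            normalize = "unit-sum", n_reps = 20L, seed = 1L,
                            dnb_genes = NULL) {
  m <- as_expr_values(x)
  pt <- pt %||% pseudotime(x)
  if (is.null(pt)) {
    abort("Pseudotime is required: supply `pt` or an expr_matrix with pseudotime.",
          class = "bifurscan_config_error")
  }
  if (length(pt) != nrow(m)) {
    abort("`pt` must have one value per cell.", class = "bifurscan_shape_error")
  }
  norm <- normalize_cells(m, normalize)
  bins <- bin_by_pseudotime(pt, bin_size = bin_size, overlap = overlap)
  out <- omega_trajectory(norm, bins)
  nul <- null_trajectory(norm, bins, n_reps = n_reps, seed = seed)
  out <- dplyr::left_join(out, nul, by = "bin")
  out <- mutate(out,
                null_mean_shifted = .data$null_mean - min(.data$null_mean),
                z = (.data$omega1 - .data$null_mean) /
                  pmax(.data$null_sd, .Machine$double.eps))
  if (!is.null(dnb_genes)) {
    out$dnb <- map_dbl(bins$cells, function(idx) {
      dnb_order_parameter(norm[idx, , drop = FALSE], dnb_genes)
    })
  }
  attr(out, "bins") <- bins
  attr(out, "normalize") <- normalize
  class(out) <- c("omega_scan", class(out))
  out
}

#' Classify transition events in an eigenvalue trajectory
#'
#' Scans the per-bin z-scores of an [scan_trajectory()] result for three
#' signatures: a *one-to-one spike* (isolated local maximum with
#' `z >= z_spike` that returns below `z_onset` within `window` bins on both
#' sides, the saddle-node signature); a *one-to-many onset* (first bin of a
#' run of at least `run_length` bins with `z >= z_onset` and nonnegative
#' trend, the pitchfork signature); and a *step-like* change-point between
#' two low-slope plateaus at different levels (the noise-induced-transition
#' signature), searched only when neither of the first two is found.
#'
#' @param scan An `omega_scan` tibble (or any tibble with `bin` and `z`).
#' @param z_spike Spike threshold. Default 5.
#' @param z_onset Onset / return threshold. Default 2.
#' @param run_length Minimum run length for an onset. Default 10.
#' @param window Bins within which a spike must return below `z_onset`.
#'   Default 5.
#' @param step_min_levels Minimum plateau-level difference (in z units) for
#'   a step. Default `z_onset`.
#' @return A tibble of class `transition_report`: `bin`, `class`
#'   (`"one-to-one spike"`, `"one-to-many onset"`, or `"step-like"`), `z`,
#'   `window_start`, `window_end`; zero rows when nothing is detected.
#' @export
classify_transitions <- function(scan, z_spike = 5, z_onset = 2,
                                 run_length = 10L, window = 5L,
                                 step_min_levels = z_onset) {
  for (nm in c("z_spike", "z_onset", "window", "run_length")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0) {
      abort(sprintf("`%s` must be positive.", nm), class = "bifurscan_config_error")
    }
  }
  z <- scan$z
  bins <- scan$bin
  n <- length(z)
  if (n < 5L) {
    abort("At least 5 bins are required to classify transitions.",
          class = "bifurscan_config_error")
  }
  events <- list()

  # one-to-one spikes
  for (i in seq_len(n)) {
    if (z[i] < z_spike) next
    if (i > 1L && z[i] < z[i - 1L]) next
    if (i < n && z[i] < z[i + 1L]) next
    if (i > 1L && i < n && z[i] == z[i + 1L]) next  # plateau: keep right-most
    left <- if (i == 1L) TRUE else {
      lo <- max(1L, i - window)
      any(z[lo:(i - 1L)] < z_onset)
    }
    right <- if (i == n) TRUE else {
      hi <- min(n, i + window)
      any(z[(i + 1L):hi] < z_onset)
    }
    if (left && right) {
      events <- c(events, list(tibble(
        bin = bins[i], class = "one-to-one spike", z = z[i],
        window_start = bins[max(1L, i - window)],
        window_end = bins[min(n, i + window)])))
    }
  }

  # step-like change-point: two flat plateaus at different levels. Checked
  # before onsets because a step's upper plateau also satisfies the onset
  # run criteria; checked only when no spike explains the curve.
  step_found <- FALSE
  if (length(events) == 0L && n >= 2L * 3L) {
    best <- find_step(z, min_seg = 3L, min_diff = step_min_levels)
    if (!is.null(best)) {
      step_found <- TRUE
      events <- c(events, list(tibble(
        bin = bins[best$cp], class = "step-like", z = z[best$cp],
        window_start = bins[1L], window_end = bins[n])))
    }
  }

  # one-to-many onsets: maximal runs of z >= z_onset with nonnegative trend.
  # A run may contain a spike (a ramp building to a one-to-one event reports
  # both, mirroring trajectories with a decision followed by maturation).
  if (!step_found) {
    above <- z >= z_onset
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (!r$values[j] || r$lengths[j] < run_length) next
      seg <- starts[j]:ends[j]
      trend <- stats::coef(stats::lm(z[seg] ~ seq_along(seg)))[2L]
      if (trend >= 0) {
        events <- c(events, list(tibble(
          bin = bins[starts[j]], class = "one-to-many onset", z = z[starts[j]],
          window_start = bins[starts[j]], window_end = bins[ends[j]])))
      }
    }
  }

  out <- if (length(events) == 0L) {
    tibble(bin = integer(), class = character(), z = numeric(),
           window_start = integer(), window_end = integer())
  } else {
    arrange(bind_rows(events), .data$bin)
  }
  attr(out, "thresholds") <- list(z_spike = z_spike, z_onset = z_onset,
                                  run_length = run_length, window = window,
                                  step_min_levels = step_min_levels)
  class(out) <- c("transition_report", class(out))
  out
}

# Two-plateau change-point: both segments must be flat (slope small relative
# to the level difference) and separated by at least `min_diff`.
find_step <- function(z, min_seg = 3L, min_diff = 2) {
  n <- length(z)
  best <- NULL
  for (cp in seq.int(min_seg + 1L, n - min_seg + 1L)) {
    a <- z[1:(cp - 1L)]; b <- z[cp:n]
    diff_lvl <- abs(mean(b) - mean(a))
    if (diff_lvl < min_diff) next
    slope_a <- abs(stats::coef(stats::lm(a ~ seq_along(a)))[2L]) * length(a)
    slope_b <- abs(stats::coef(stats::lm(b ~ seq_along(b)))[2L]) * length(b)
    if (slope_a > 0.5 * diff_lvl || slope_b > 0.5 * diff_lvl) next
    pooled_sd <- sqrt((sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n - 2L))
    if (diff_lvl < 3 * pooled_sd) next
    score <- diff_lvl / max(pooled_sd, .Machine$double.eps)
    if (is.null(best) || score > best$score) best <- list(cp = cp, score = score)
  }
  best
}
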