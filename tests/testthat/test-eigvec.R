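test_that("eigenvector series keeps gene order and unit norms", {
  fx <- generate_fixture(n_cells = 600, n_genes = 15, n_groups = 12,
                         class = "one-to-many", seed = 2)
  bins <- bin_by_pseudotime(pseudotime(fx), 50, 0.5)
  es <- eigvec_series(fx, bins)
  expect_equal(rownames(es$loadings), colnames(fx))
  norms <- sqrt(colSums(es$loadings^2))
  expect_equal(unname(norms), rep(1, ncol(es$loadings)), tolerance = 1e-10)
  td <- tidy(es)
  expect_equal(nrow(td), 15L * nrow(bins))
})

test_that("eigenvector correlation maps recover planted epoch blocks", {
  # one shared direction: all-ones map
  v <- c(0.5, -0.5, 0.5, 0.5)
  L <- matrix(rep(v, 4), ncol = 4)
  R <- eigvec_correlation_map(L)
  expect_equal(unclass(R), matrix(1, 4, 4), ignore_attr = TRUE)

  # orthogonal zero-mean loading vectors: off-diagonal zero
  L2 <- cbind(c(1, -1, 1, -1) / 2, c(1, 1, -1, -1) / 2)
  R2 <- eigvec_correlation_map(L2)
  expect_equal(R2[1, 2], 0, tolerance = 1e-12)

  # two epochs with distinct planted directions, recovered by thresholding
  set.seed(14)
  a <- rnorm(30); a <- a - mean(a); a <- a / sqrt(sum(a^2))
  b <- rnorm(30); b <- b - mean(b)
  b <- b - a * sum(a * b); b <- b / sqrt(sum(b^2))
  noise <- function(v) { w <- v + rnorm(30, sd = 0.05); w / sqrt(sum(w^2)) }
  L3 <- cbind(noise(a), noise(a), noise(a), noise(b), noise(b), noise(b))
  R3 <- unclass(eigvec_correlation_map(L3))
  within <- c(R3[1:3, 1:3][upper.tri(diag(3))], R3[4:6, 4:6][upper.tri(diag(3))])
  across <- as.vector(R3[1:3, 4:6])
  expect_true(all(abs(within) > 0.5))
  expect_true(all(abs(across) < 0.5))

  expect_error_class(eigvec_correlation_map(L3[, 1, drop = FALSE]),
                     "bifurscan_config_error")
  L3[1, 1] <- NA
  expect_error_class(eigvec_correlation_map(L3), "bifurscan_alignment_error")
})

test_that("projections behave like coordinates along a unit direction", {
  set.seed(4)
  m <- matrix(rexp(50), 10, 5, dimnames = list(paste0("c", 1:10), paste0("g", 1:5)))
  # basis vector picks out one gene
  p <- project_cells(m, c(0, 0, 1, 0, 0))
  expect_equal(p$projection, unname(m[, 3]))
  # orthogonal direction: all zeros
  m0 <- matrix(rep(c(1, 1, 0, 0), 6), 6, 4, byrow = TRUE)
  expect_equal(project_cells(m0, c(0, 0, 1, -1))$projection, rep(0, 6))
  # rank-1 rows: coordinates proportional to the amplitudes
  v <- c(3, 4) / 5
  a <- c(1, 2, 5)
  expect_equal(project_cells(a %o% v, 2 * v)$projection, a)
  expect_error_class(project_cells(m, 1:3), "bifurscan_shape_error")
  expect_error_class(project_cells(m, rep(0, 5)), "bifurscan_domain_error")
})

test_that("variance fractions follow the Rayleigh quotient", {
  set.seed(26)
  x <- matrix(rnorm(600), 100, 6) %*% diag(c(3, 2, 1, 1, 1, 1))
  ce <- covariance_eig(x)
  vf <- variance_fraction(x, ce$vectors[, 1])
  expect_equal(vf, ce$values[1] / sum(ce$values), tolerance = 1e-10)
  # any other unit vector explains less
  expect_lt(variance_fraction(x, rep(1, 6)), vf)
  # isotropic data: roughly 1/n_genes in any direction
  iso <- matrix(rnorm(6000), 1000, 6)
  expect_equal(variance_fraction(iso, rnorm(6)), 1 / 6, tolerance = 0.05)
  # direction orthogonal to all variation
  flat <- cbind(rnorm(50), 0)
  expect_equal(variance_fraction(flat, c(0, 1)), 0)
  expect_error_class(variance_fraction(matrix(1, 5, 2), c(1, 0)),
                     "bifurscan_domain_error")
})

test_that("projection distributions flag only genuine bimodality", {
  set.seed(44)
  n <- 300; g <- 8
  v <- rnorm(g); v <- v / sqrt(sum(v^2))
  uni <- 10 + matrix(rnorm(n * g), n, g)
  bim <- 10 + matrix(rnorm(n * g), n, g) + (6 * rbinom(n, 1, 0.5)) %o% v
  bins <- bin_by_pseudotime(rep(1:2, each = n), n, 0)
  pd <- projection_distribution(rbind(uni, bim), bins, v)
  expect_false(pd$bimodal[1])
  expect_true(pd$bimodal[2])
  expect_gt(pd$delta_bic[2], 10)
})

test_that("category weights average absolute loadings with matching rules", {
  w <- category_weights(c(a = 0.6, b = -0.8), list(set1 = c("a", "b")))
  expect_equal(w$weight, 0.7)

  # equal-loading unit vector: every gene contributes 1/sqrt(n)
  n <- 16
  v <- setNames(rep(1 / sqrt(n), n), paste0("g", 1:n))
  w2 <- category_weights(v, list(all = names(v)))
  expect_equal(w2$weight, 1 / sqrt(n))

  # unmatched genes are ignored and counted; empty categories dropped
  w3 <- category_weights(c(a = 0.5, b = 0.1),
                         list(mixed = c("a", "zz"), gone = c("q", "r")))
  expect_equal(w3$category, "mixed")
  expect_equal(w3$n_unmatched, 1L)
  expect_error_class(category_weights(c(a = 1), list(gone = "zz")),
                     "bifurscan_set_error")

  # signed option and monotonicity in member loadings
  ws <- category_weights(c(a = 0.6, b = -0.8), list(s = c("a", "b")),
                         signed = TRUE)
  expect_equal(ws$weight, -0.1)
  w_lo <- category_weights(c(a = 0.2, b = 0.4, c = 0.9), list(s = c("a", "b")))
  w_hi <- category_weights(c(a = 0.3, b = 0.4, c = 0.9), list(s = c("a", "b")))
  expect_gt(w_hi$weight, w_lo$weight)

  # permutation invariance in gene order
  v4 <- c(a = 0.1, b = 0.7, c = -0.3)
  expect_equal(category_weights(v4, list(s = c("a", "c")))$weight,
               category_weights(rev(v4), list(s = c("c", "a")))$weight)
})

test_that("mixture split recovers planted clusters deterministically", {
  set.seed(52)
  n <- 500; g <- 12
  v <- rnorm(g); v <- v / sqrt(sum(v^2))
  truth <- rep(c(0, 1), each = n / 2)
  X <- 10 + matrix(rnorm(n * g), n, g) + (6 * truth) %o% v
  X[X < 0] <- 0
  sp <- fit_mixture_split(X, seed = 7)
  agree <- max(mean((sp$labels$label == "a") == (truth == 0)),
               mean((sp$labels$label == "a") == (truth == 1)))
  expect_gte(agree, 0.99)
  expect_gt(sp$delta_bic, 10)

  sp2 <- fit_mixture_split(X, seed = 7)
  expect_identical(sp$labels$label, sp2$labels$label)

  # a single Gaussian shows no evidence for two components
  X1 <- 10 + matrix(rnorm(n * g), n, g)
  expect_lt(fit_mixture_split(X1, seed = 7)$delta_bic, 10)

  expect_error_class(fit_mixture_split(matrix(1, 30, 4)),
                     "bifurscan_degeneracy_error")
  expect_error_class(fit_mixture_split(X[1:10, ]), "bifurscan_config_error")
})

test_that("label propagation reproduces training labels and planted onsets", {
  set.seed(58)
  n <- 600; g <- 10
  v <- rnorm(g); v <- v / sqrt(sum(v^2))
  # cluster b appears only in the second half of pseudotime
  second <- c(rep(0, n / 2), rbinom(n / 2, 1, 0.5))
  X <- 10 + matrix(rnorm(n * g), n, g) + (7 * second) %o% v
  X[X < 0] <- 0
  dimnames(X) <- list(paste0("c", 1:n), paste0("g", 1:g))
  bins <- bin_by_pseudotime(seq_len(n), 100, 0)

  train_idx <- bins$cells[[5]]
  sp <- fit_mixture_split(X[train_idx, ], seed = 3)
  pr <- propagate_labels(sp, X, bins)
  # training bin reproduces training labels (borderline cells may flip at
  # numerical precision, so agreement rather than identity)
  cl <- attr(pr, "cell_labels")
  expect_gte(mean(cl$label[train_idx] == sp$labels$label), 0.99)
  # before the onset the composition is (almost) purely one cluster,
  # afterwards it is genuinely mixed
  expect_gt(max(pr$frac_a[1:3], pr$frac_b[1:3]), 0.95)
  expect_true(all(pmax(pr$frac_a[5:6], pr$frac_b[5:6]) < 0.95))

  expect_error_class(propagate_labels(sp, X[, c(2:g, 1)], bins),
                     "bifurscan_mapping_error")
})

test_that("splitting branches recovers tight per-branch covariance", {
  # past the pitchfork the pooled spectrum mixes two branches; clustering
  # cells by transcriptomic mode collapses omega1 to the within-branch scale
  net <- grn_network(n_genes = 12, n_cells = 200, m1 = 1, m2 = 1, k_d = 0.3,
                     n_steps = 3000, seed = 71)
  G <- grn_simulate(net)
  pooled <- covariance_eig(G, k = 1)$values[1]
  sp <- fit_mixture_split(G, d = 5, seed = 2)
  per <- sapply(c("a", "b"), function(cl) {
    covariance_eig(unclass(G)[sp$labels$label == cl, , drop = FALSE],
                   k = 1)$values[1]
  })
  expect_lt(max(per), 0.3 * pooled)
})
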