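test_that("cell normalization modes behave as documented", {
  m <- matrix(c(1, 1, 2), 1, 3)
  expect_equal(unname(normalize_cells(m)), matrix(c(0.25, 0.25, 0.5), 1))
  # already normalized rows unchanged
  n <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, byrow = TRUE)
  expect_equal(unname(normalize_cells(n)), n)
  # median-count preserves relative profiles and equalizes totals
  x <- rbind(c(1, 3), c(2, 6), c(10, 30))
  mc <- normalize_cells(x, "median-count")
  expect_equal(unname(rowSums(mc)), rep(8, 3))
  expect_equal(unname(normalize_cells(x, "none")), x)
  z <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("ok", "empty"), NULL))
  expect_error(normalize_cells(z), "empty", class = "bifurscan_zero_row_error")
})

test_that("binning arithmetic matches the published layout", {
  b <- bin_by_pseudotime(61310, bin_size = 1000, overlap = 0.5)
  expect_equal(nrow(b), 121L)
  expect_equal(b$n_cells[121], 1310L)
  expect_true(all(b$n_cells[-121] == 1000L))
  expect_equal(b$bin, 1:121)

  expect_equal(nrow(bin_by_pseudotime(1000, 1000)), 1L)

  b4 <- bin_by_pseudotime(2500, 1000, 0.5)
  expect_equal(b4$n_cells, rep(1000L, 4))
  expect_equal(sapply(b4$cells, min), c(1L, 501L, 1001L, 1501L))

  expect_error_class(bin_by_pseudotime(10, 100), "bifurscan_binning_error")
  expect_error_class(bin_by_pseudotime(100, 10, overlap = 1),
                     "bifurscan_config_error")
})

test_that("binning count formula and coverage hold for random settings", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(50:5000, 1)
    bs <- sample(10:min(n, 500), 1)
    ov <- sample(c(0, 0.25, 0.5, 0.75), 1)
    b <- bin_by_pseudotime(n, bs, ov)
    step <- max(1L, as.integer(round(bs * (1 - ov))))
    expect_equal(nrow(b), floor((n - bs) / step) + 1L)
    expect_setequal(unlist(b$cells), seq_len(n))          # every cell covered
    expect_true(all(b$n_cells[-nrow(b)] == bs))           # full bins exact
    expect_true(b$n_cells[nrow(b)] >= bs && b$n_cells[nrow(b)] < bs + step)
    expect_false(is.unsorted(b$mean_pseudotime))
  }
})

test_that("bins sort by pseudotime with stable tie-breaking", {
  pt <- c(3, 1, 2, 1, 2)
  b <- bin_by_pseudotime(pt, 2, overlap = 0)
  expect_equal(b$cells[[1]], c(2L, 4L))  # ties keep input order
  expect_equal(b$cells[[2]], c(3L, 5L, 1L))  # final bin absorbs the tail
})

test_that("omega trajectory is structure-free on iid data, gene-order invariant", {
  set.seed(23)
  x <- matrix(rnorm(1200 * 20, mean = 10), 1200, 20)
  bins <- bin_by_pseudotime(1200, 100, 0.5)
  om <- omega_trajectory(x, bins)
  expect_equal(min(om$omega1_shifted), 0)
  nul <- null_trajectory(x, bins, n_reps = 20, seed = 5)
  expect_true(all(om$omega1 < nul$null_mean + 5 * nul$null_sd))

  perm <- sample(20)
  om2 <- omega_trajectory(x[, perm], bins)
  expect_equal(om$omega1, om2$omega1, tolerance = 1e-10)
})

test_that("the gene-shuffled null preserves marginals and kills correlation", {
  # single gene: permutation leaves omega1 exactly unchanged
  set.seed(31)
  x1 <- matrix(rexp(200), 200, 1)
  b1 <- bin_by_pseudotime(200, 100, 0)
  nul <- null_trajectory(x1, b1, n_reps = 5, seed = 1)
  om <- omega_trajectory(x1, b1)
  expect_equal(nul$null_mean, om$omega1, tolerance = 1e-12)
  expect_equal(nul$null_sd, c(0, 0), tolerance = 1e-12)

  # strong gene-gene correlation: data far above the null
  sw <- small_sweep()
  G3 <- sw$matrix[[match(3, sw$control_value)]]
  ball <- bin_by_pseudotime(nrow(G3), nrow(G3))
  omg <- omega_trajectory(G3, ball)$omega1
  nn <- null_trajectory(G3, ball, n_reps = 20, seed = 2)
  expect_gt(omg, nn$null_mean + 5 * nn$null_sd)
})

test_that("transition classification identifies the three signatures", {
  flat <- tibble::tibble(bin = 1:40, z = rep(0, 40))
  expect_equal(nrow(classify_transitions(flat)), 0L)

  spike <- tibble::tibble(bin = 1:40, z = replace(rep(0, 40), 17, 8))
  rs <- classify_transitions(spike)
  expect_equal(rs$class, "one-to-one spike")
  expect_equal(rs$bin, 17L)

  ramp <- tibble::tibble(bin = 1:60, z = pmax(0, (1:60 - 29) * 0.5))
  rr <- classify_transitions(ramp)
  expect_true("one-to-many onset" %in% rr$class)
  onset <- rr$bin[rr$class == "one-to-many onset"]
  expect_true(abs(onset - 33) <= 1)  # first bin with z >= 2 on this ramp

  set.seed(9)
  stepz <- tibble::tibble(bin = 1:40,
                          z = c(rep(0, 20), rep(4, 20)) + rnorm(40, sd = 0.2))
  rt <- classify_transitions(stepz)
  expect_equal(rt$class, "step-like")
  expect_true(abs(rt$bin - 21) <= 1)

  expect_error_class(classify_transitions(flat, z_spike = -1),
                     "bifurscan_config_error")
  expect_error_class(classify_transitions(flat[1:3, ]), "bifurscan_config_error")
})

test_that("DNB order parameter arithmetic matches the composite index", {
  # constructed so within-DNB |PCC| = 1, cross |PCC| = 1/2, DNB sds = 2
  x <- c(-1.5, -0.5, 0.5, 1.5)
  w <- c(1, -1, -1, 1)
  y <- x + sqrt(3) * w * sd(x) / sd(w)
  d1 <- 10 + x * 2 / sd(x)
  m <- cbind(d1 = d1, d2 = d1, y = 10 + y)
  expect_equal(dnb_order_parameter(m, c("d1", "d2")), 4, tolerance = 1e-4)

  expect_error_class(dnb_order_parameter(m, character(0)), "bifurscan_set_error")
  expect_error_class(dnb_order_parameter(m, colnames(m)), "bifurscan_set_error")
  expect_error_class(dnb_order_parameter(m, "nope"), "bifurscan_set_error")
})

test_that("DNB with informed genes peaks with omega1 on the sweep", {
  net <- small_net()
  sw <- small_sweep()
  td <- tidy(net)
  dnb <- c("g1", "g2", td$gene[!is.na(td$alpha) & abs(td$alpha - 0.5) > 0.25])
  om <- sapply(sw$matrix, function(m) covariance_eig(m, k = 1)$values[1])
  dn <- sapply(sw$matrix, function(m) dnb_order_parameter(m, dnb))
  expect_equal(which.max(dn), which.max(om))
  expect_equal(sw$control_value[which.max(om)], 3)
})

test_that("scan pipeline is deterministic with complete output", {
  fx <- generate_fixture(n_cells = 800, n_genes = 20, n_groups = 16,
                         class = "one-to-one", seed = 6)
  s1 <- scan_trajectory(fx, bin_size = 50, overlap = 0.5, normalize = "none",
                        n_reps = 10, seed = 3, dnb_genes = paste0("gene_", 1:5))
  s2 <- scan_trajectory(fx, bin_size = 50, overlap = 0.5, normalize = "none",
                        n_reps = 10, seed = 3, dnb_genes = paste0("gene_", 1:5))
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  expect_true(all(c("bin", "n_cells", "mean_pseudotime", "omega1",
                    "omega1_shifted", "null_mean", "null_mean_shifted",
                    "null_sd", "z", "dnb") %in% names(s1)))
  expect_equal(min(s1$omega1_shifted), 0)
  expect_equal(min(s1$null_mean_shifted), 0)
  expect_true(all(s1$null_sd >= 0))
})
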