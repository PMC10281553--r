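test_that("network construction is balanced, reproducible, and validated", {
  # degenerate: drivers only
  net2 <- grn_network(n_genes = 2, seed = 1)
  expect_length(net2$alpha, 0)
  expect_length(net2$driver_of, 0)

  net <- grn_network(n_genes = 102, seed = 7)
  expect_equal(unname(table(net$driver_of)), c(50L, 50L), ignore_attr = TRUE)
  expect_true(all(net$alpha >= 0 & net$alpha <= 1))
  # deterministic given seed
  expect_identical(net$alpha, grn_network(n_genes = 102, seed = 7)$alpha)
  expect_false(identical(net$alpha, grn_network(n_genes = 102, seed = 8)$alpha))

  # constant coupling: both responders fully inhibited
  net0 <- grn_network(n_genes = 4, alpha_sampling = 0)
  expect_equal(net0$alpha, c(0, 0))

  expect_error_class(grn_network(n_genes = 1), "bifurscan_invalid_network")
  expect_error_class(grn_network(n_genes = 4, k_d = -1), "bifurscan_config_error")

  td <- tidy(net)
  expect_equal(nrow(td), 102L)
  expect_equal(sum(td$role == "driver"), 2L)
  expect_equal(glance(net)$n_genes, 102L)
})

test_that("drift matches hand-computed rates and rejects bad states", {
  # balanced drivers: -0.5 * 1 + 1 / (1 + 1) = 0
  net <- grn_network(n_genes = 2, m1 = 1, m2 = 1, k_d = 0.5)
  expect_equal(grn_drift(c(1, 1), net), c(0, 0))

  # synthesis only at the origin
  net1 <- grn_network(n_genes = 2, m1 = 1, m2 = 1, k_d = 1)
  expect_equal(grn_drift(c(0, 0), net1), c(1, 1))

  # activating responder: steady value m * (g_d^2 / (1 + g_d^2)) / k = 1
  net3 <- grn_network(n_genes = 3, m1 = 2, m2 = 2, k_d = 1, k_resp = 1,
                      alpha_sampling = 1)
  expect_equal(grn_drift(c(1, 1, 1), net3)[3], 0)

  expect_error_class(grn_drift(c(-1, 1), net), "bifurscan_domain_error")
  expect_error_class(grn_drift(c(1, 1, 1), net), "bifurscan_domain_error")
})

test_that("jacobian agrees with closed form and finite differences", {
  net <- grn_network(n_genes = 2, m1 = 1, m2 = 1, k_d = 0.5)
  J <- grn_jacobian(c(1, 1), net)
  expect_equal(unname(J), matrix(c(-0.5, -0.5, -0.5, -0.5), 2), tolerance = 1e-12)
  ev <- sort(eigen(J, only.values = TRUE)$values)
  expect_equal(ev, c(-1, 0), tolerance = 1e-12)

  # central finite differences on random states of a heterogeneous network
  netr <- grn_network(n_genes = 8, m1 = 2.3, m2 = 1.7, k_d = 0.8,
                      k_resp = c(1, 1.5, 0.7, 2, 1.2, 0.9), seed = 3)
  set.seed(5)
  h <- 1e-6
  for (rep in 1:5) {
    s <- runif(8, 0.1, 3)
    J <- grn_jacobian(s, netr)
    expect_equal(unname(diag(J)), -c(0.8, 0.8, netr$k_resp))
    Jfd <- sapply(1:8, function(j) {
      sp <- s; sm <- s
      sp[j] <- sp[j] + h; sm[j] <- sm[j] - h
      (grn_drift(sp, netr) - grn_drift(sm, netr)) / (2 * h)
    })
    expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-6)
  }
})

test_that("fixed points match one-dimensional bisection oracles", {
  # single stable symmetric point: g (1 + g^2) = 1
  g_star <- uniroot(function(g) g * (1 + g^2) - 1, c(0, 2), tol = 1e-12)$root
  fp <- grn_fixed_points(grn_network(n_genes = 2, m1 = 1, m2 = 1, k_d = 1))
  expect_equal(nrow(fp), 1L)
  expect_true(fp$stable)
  expect_equal(fp$g1, g_star, tolerance = 1e-8)
  expect_equal(fp$g1, 0.6823, tolerance = 1e-4)

  # bistable: unstable symmetric point flanked by two stable asymmetric ones
  fp3 <- grn_fixed_points(grn_network(n_genes = 2, m1 = 3, m2 = 3, k_d = 1))
  expect_equal(nrow(fp3), 3L)
  expect_equal(fp3$stable, c(TRUE, FALSE, TRUE))
  sym <- fp3[2, ]
  expect_equal(sym$g1, sym$g2, tolerance = 1e-8)
  expect_equal(sym$g1, uniroot(function(g) g * (1 + g^2) - 3, c(0, 3),
                               tol = 1e-12)$root, tolerance = 1e-8)
  # the two stable points are mirror images
  expect_equal(fp3$g1[1], fp3$g2[3], tolerance = 1e-8)

  # pitchfork threshold: symmetric point at g* = 1 with marginal stability
  # (triple root of the reduced residual, so the location is only resolved
  # to about the cube root of the solver tolerance)
  fpc <- grn_fixed_points(grn_network(n_genes = 2, m1 = 1, m2 = 1, k_d = 0.5))
  expect_equal(fpc$g1[1], 1, tolerance = 1e-4)
  expect_equal(fpc$lambda_d[1], 0, tolerance = 1e-7)

  # responder components solved in closed form
  net <- grn_network(n_genes = 4, m1 = 1, m2 = 1, k_d = 1, alpha_sampling = 1)
  st <- grn_fixed_points(net)$state[[1]]
  expect_lt(max(abs(grn_drift(st, net))), 1e-8)
})

test_that("critical-control bisection finds both printed thresholds", {
  net <- grn_network(n_genes = 2, m1 = 1, m2 = 1)
  cr <- grn_critical(net, "k_d", c(0.24, 5))
  expect_equal(cr$critical_value, 0.5, tolerance = 1e-6)

  # stable throughout the bracket: no crossing
  expect_error_class(grn_critical(net, "k_d", c(1, 5)), "bifurscan_bracket_error")

  # balanced double well of the saddle-node pair
  net_m <- grn_network(n_genes = 2, m1 = 2, m2 = 3, k_d = 1)
  crm <- grn_critical(net_m, "m1", c(2.75, 3.5))
  expect_equal(crm$criterion, "balance")
  expect_equal(crm$critical_value, 3, tolerance = 1e-6)
})

test_that("simulation is reproducible and recovers the deterministic limit", {
  net <- grn_network(n_genes = 4, n_cells = 5, m1 = 1, m2 = 1, k_d = 1,
                     noise = 0, n_steps = 4000, seed = 9)
  G <- grn_simulate(net)
  expect_s3_class(G, "expr_matrix")
  st <- grn_fixed_points(net)$state[[1]]
  expect_lt(max(abs(sweep(unclass(G), 2, st))), 1e-3)

  # determinism
  netn <- grn_network(n_genes = 5, n_cells = 20, n_steps = 500, seed = 4)
  expect_identical(unclass(grn_simulate(netn)), unclass(grn_simulate(netn)))
  expect_false(identical(unclass(grn_simulate(netn, seed = 5)),
                         unclass(grn_simulate(netn))))
})

test_that("driver expression is bimodal at the balanced saddle-node point", {
  net <- grn_network(n_genes = 2, n_cells = 100, m1 = 3, m2 = 3, k_d = 1,
                     n_steps = 4000, seed = 12)
  G <- grn_simulate(net)
  # two-component mixture strongly preferred by BIC
  expect_gt(bifurscan:::mixture_evidence(G[, 1]), 10)
})

test_that("sweeps derive child seeds deterministically and track the branch", {
  net <- small_net()
  one <- grn_sweep(net, "m1", 2.5, seed = 20)
  expect_equal(nrow(one), 1L)
  p <- net; p$m1 <- 2.5
  expect_identical(unclass(one$matrix[[1]]),
                   unclass(grn_simulate(p, seed = bifurscan:::derive_seed(20, 1))))

  sw <- small_sweep()
  mean_g1 <- sapply(sw$matrix, function(m) mean(m[, 1]))
  # driver g1 rises with its synthesis scale, with the largest jump at the
  # state switch next to the balanced point m1 = 3
  expect_gt(mean_g1[5], mean_g1[1])
  inc <- diff(mean_g1)
  expect_true(which.max(inc) %in% c(2L, 3L))
})

test_that("symmetric networks give symmetric marginal statistics", {
  net <- grn_network(n_genes = 6, n_cells = 300, m1 = 1, m2 = 1, k_d = 1,
                     alpha_sampling = 0.7, n_steps = 2000, seed = 33)
  G <- grn_simulate(net)
  # g1 <-> g2 and responders-of-1 <-> responders-of-2 have matched alpha here
  expect_lt(abs(mean(G[, 1]) - mean(G[, 2])), 3 * sd(G[, 1]) / sqrt(300) * 2)
  resp1 <- colMeans(G[, c(3, 5)]); resp2 <- colMeans(G[, c(4, 6)])
  expect_lt(max(abs(resp1 - resp2)), 0.1)
})

test_that("stationary fluctuations match the Lyapunov prediction", {
  net <- grn_network(n_genes = 4, n_cells = 400, m1 = 1, m2 = 1, k_d = 1,
                     noise = 0.05, n_steps = 3000, seed = 11)
  G <- grn_simulate(net)
  st <- grn_fixed_points(net)$state[[1]]
  C <- solve_lyapunov(grn_jacobian(st, net), grn_noise_covariance(st, net))$C
  v_emp <- apply(unclass(G), 2, var)
  se <- diag(C) * sqrt(2 / (400 - 1))
  expect_true(all(abs(v_emp - diag(C)) < 3 * se))
})
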