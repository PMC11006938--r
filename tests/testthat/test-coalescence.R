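test_that("coalescence times match hand-solved cases", {
  ct2 <- solve_coalescence(k2(), 1)
  expect_equal(ct2$eta[1, 2], 0.5, tolerance = 1e-12)

  ct3 <- solve_coalescence(k3(), 1)
  expect_equal(ct3$eta[upper.tri(ct3$eta)], rep(1, 3), tolerance = 1e-12)

  expect_equal(diag(ct3$eta), rep(0, 3))
  expect_identical(ct3$eta, t(ct3$eta))
  expect_lt(ct3$residual, 1e-10)
})

test_that("the three solvers agree on random graphs and rates", {
  set.seed(11)
  for (rep in 1:5) {
    net <- random_connected(sample(5:12, 1))
    lam <- runif(net$N, 0.2, 3)
    e_pairs <- solve_coalescence(net, lam, method = "pairs")$eta
    e_eig <- solve_coalescence(net, lam, method = "eigen")$eta
    e_fp <- solve_coalescence(net, lam, method = "fixed_point")$eta
    expect_lt(max(abs(e_pairs - e_eig)), 1e-10 * max(1, max(e_pairs)))
    expect_lt(max(abs(e_pairs - e_fp)), 1e-8 * max(1, max(e_pairs)))
  }
})

test_that("coalescence times depend on rates only through ratios", {
  set.seed(3)
  net <- random_connected(8)
  lam <- runif(8, 0.5, 2)
  e1 <- solve_coalescence(net, lam)$eta
  e2 <- solve_coalescence(net, 17 * lam)$eta
  expect_lt(max(abs(e1 - e2)) / max(e1), 1e-12)
})

test_that("the general solver reduces to the identical-rate recurrence", {
  set.seed(4)
  for (net in list(cycle_n(7), random_connected(10),
                   generate_network("scale_free_ba", N = 15, seed = 2))) {
    e_gen <- solve_coalescence(net, 1)$eta
    e_id <- coopfix:::solve_eta_identical(net)
    expect_lt(max(abs(e_gen - e_id)), 1e-11 * max(1, max(e_id)))
  }
})

test_that("solver stays exact when rates span many orders of magnitude", {
  set.seed(9)
  net <- generate_network("scale_free_ba", N = 40, seed = 9)
  lam <- exp(rnorm(40, 0, 10))
  ct <- solve_coalescence(net, lam)
  expect_lt(ct$residual, 1e-10 * max(1, max(ct$eta)))
  expect_true(all(ct$eta[upper.tri(ct$eta)] > 0))
})

test_that("reproductive values weight degree over update rate", {
  expect_equal(reproductive_values(cycle_n(8), 1)$pi, rep(1 / 8, 8))
  expect_equal(reproductive_values(k2(), c(1, 3))$pi, c(3 / 4, 1 / 4))
  set.seed(5)
  net <- random_connected(9)
  lam <- runif(9, 0.3, 2)
  pv <- reproductive_values(net, lam)$pi
  expect_equal(sum(pv), 1)
  expect_true(all(pv > 0))
})

test_that("the weighted cooperator frequency is a neutral martingale", {
  # E[d x_hat | x] = sum_i pi_i sum_j (x_j - x_i) (lambda_i/Lambda) p_ij = 0
  set.seed(6)
  net <- random_connected(10)
  lam <- runif(10, 0.2, 4)
  pv <- reproductive_values(net, lam)$pi
  P <- net$adj / net$deg
  for (rep in 1:20) {
    x <- rbinom(10, 1, 0.5)
    drift <- sum(pv * (lam / sum(lam)) * as.vector(P %*% x - x))
    expect_lt(abs(drift), 1e-14)
  }
})

test_that("rate profiles implement the documented schemes", {
  ds <- generate_network("double_star", params = list(leaves = 5))
  rp <- rate_profile(ds, "power", gamma = -1)
  expect_equal(rp$lambda[ds$deg == 6], rep(1 / 6, 2))
  expect_equal(rp$lambda[ds$deg == 1], rep(1, 10))

  id <- rate_profile(ds, "identical")
  expect_equal(id$lambda, rep(1, 12))
  expect_equal(id$Lambda, 12)

  for (scheme in c("uniform", "normal", "exponential", "power_law")) {
    a <- rate_profile(ds, scheme, seed = 1)
    b <- rate_profile(ds, scheme, seed = 1)
    c <- rate_profile(ds, scheme, seed = 2)
    expect_identical(a$lambda, b$lambda, info = scheme)
    expect_false(identical(a$lambda, c$lambda), info = scheme)
    expect_true(all(a$lambda > 0) && all(c$lambda > 0), info = scheme)
  }
  expect_error(new_rate_profile(c(1, -1)), "positive")
  expect_error(rate_profile(ds, "uniform", params = list(min = -1, max = 2)))
})

test_that("walk operators are stochastic and consistent", {
  net <- path3()
  ops <- step_matrices(net)
  expect_equal(ops$p[2, ], c(0.5, 0, 0.5))
  expect_equal(ops$p[1, 2], 1)
  expect_equal(ops$p2[1, 1], 0.5)  # a -> b -> a
  for (m in list(ops$p, ops$p2, ops$p3)) {
    expect_equal(rowSums(m), rep(1, 3), tolerance = 1e-12)
    expect_true(all(m >= 0))
  }
  expect_equal(ops$p3, ops$p2 %*% ops$p)
})
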