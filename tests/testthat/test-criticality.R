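test_that("hand-derived critical ratios are reproduced", {
  res <- cstar_exact(k3(), 1)
  expect_equal(res$numerator, 3, tolerance = 1e-12)
  expect_equal(res$denominator, -1.5, tolerance = 1e-12)
  expect_equal(res$value, -2, tolerance = 1e-12)
  expect_equal(res$regime, "never_favoured")

  expect_equal(cstar_exact(cycle_n(6), 1)$value, 4, tolerance = 1e-10)
})

test_that("vertex-transitive graphs follow the closed form k(N-2)/(N-2k)", {
  for (N in c(5, 6, 7, 9)) {
    expect_equal(cstar_exact(cycle_n(N), 1)$value, regular_cstar(N, 2),
                 tolerance = 1e-10, info = paste("cycle", N))
  }
  for (N in c(3, 5, 6)) {
    expect_equal(cstar_exact(generate_network("complete", N = N), 1)$value,
                 regular_cstar(N, N - 1), tolerance = 1e-10,
                 info = paste("complete", N))
  }
  # N = 2k: the denominator vanishes and no finite threshold exists
  expect_equal(cstar_exact(cycle_n(4), 1)$regime, "divergent")
  expect_true(is.na(cstar_exact(cycle_n(4), 1)$value))
})

test_that("critical ratios are invariant to rescaling all rates", {
  set.seed(21)
  net <- generate_network("scale_free_ba", N = 30, seed = 21)
  lam <- runif(30, 0.3, 2)
  a <- cstar_exact(net, lam)$value
  b <- cstar_exact(net, 10 * lam)$value
  expect_lt(abs(a - b) / abs(a), 1e-12)
})

test_that("zeta collapses to 1/2 at identical rates", {
  for (net in list(k3(), star4(), ba100())) {
    z <- cstar_approx(net, 1)$components$zeta
    expect_equal(z, 0.5, tolerance = 1e-13)
  }
})

test_that("all four correction terms vanish at identical rates", {
  ap <- cstar_approx(ba100(), 1)
  terms <- unlist(ap$components[c("delta_lambda1", "delta_lambda2",
                                  "delta_eta_n", "delta_eta_d")])
  expect_lt(max(abs(terms)), 1e-12)
})

test_that("the mean-field expansion is exact on regular graphs at identical rates", {
  for (net in list(cycle_n(6), cycle_n(9), regular100())) {
    ex <- cstar_exact(net, 1)$value
    ap <- cstar_approx(net, 1)$value
    expect_equal(ap, ex, tolerance = 1e-10)
  }
})

test_that("the mean-field expansion tracks the exact ratio on heterogeneous inputs", {
  net <- ba100()
  lam <- rate_profile(net, "power", gamma = -1)
  ex <- cstar_exact(net, lam)$value
  ap <- cstar_approx(net, lam)$value
  # diagnostic bound: the expansion is an approximation, not exact, here
  expect_lt(abs(ap - ex) / ex, 0.5)
  ap2 <- cstar_approx(net, lam, eta_bar_mode = "supplied",
                      eta_bar = solve_coalescence(net, lam)$eta_bar)$value
  expect_true(is.finite(ap2))
})

test_that("the asymptotic sign rule classifies rate-degree coupling", {
  net <- ba100()
  expect_equal(cstar_asymptotic(net, 1)$components$classification,
               "near_mean_degree")
  lo <- cstar_asymptotic(net, rate_profile(net, "power", gamma = -1))
  hi <- cstar_asymptotic(net, rate_profile(net, "power", gamma = 1))
  expect_equal(lo$components$classification, "below_mean_degree")
  expect_equal(hi$components$classification, "above_mean_degree")
  expect_lt(lo$value, net$mean_degree)
  expect_gt(hi$value, net$mean_degree)
  # classification does not depend on the magnitude of eta_bar
  expect_equal(cstar_asymptotic(net, rate_profile(net, "power", gamma = -1),
                                eta_bar = 1e3)$components$classification,
               "below_mean_degree")
  expect_error(cstar_asymptotic(net, 1, eta_bar = -1), "positive")
})

test_that("the general game condition reduces to b/c > C* for the donation game", {
  cst <- 4
  for (bc in c(3, 4.5, 6)) {
    b <- bc
    cc <- 1
    cond <- general_game_condition(R = b - cc, S = -cc, T = b, P = 0, cst)
    expect_equal(cond$favoured, bc > cst, info = bc)
  }
  expect_equal(general_game_condition(2, 1, 3, 0.7, 1)$R_star, 0.7)
  expect_equal(general_game_condition(2, 1.5, 1.5, 0.7, 42)$R_star, 0.7)
  expect_error(general_game_condition(1, 0, 1, 0, -1), "undefined")
})

test_that("the weak-selection fixation probability behaves as derived", {
  net <- cycle_n(6)
  expect_equal(rho_c_weak_selection(net, 1, b = 3, c = 1, delta = 0)$rho, 1 / 6)
  cst <- cstar_exact(net, 1)$value
  expect_equal(rho_c_weak_selection(net, 1, b = cst, c = 1, delta = 0.4)$rho,
               1 / 6, tolerance = 1e-12)
  # two connected players: the bracket vanishes identically
  expect_equal(rho_c_weak_selection(k2(), 1, b = 7, c = 2, delta = 0.2)$rho, 0.5)
  expect_equal(rho_c_weak_selection(k2(), c(1, 3), b = 7, c = 2, delta = 0.2)$rho,
               0.5)
})

test_that("slower updating of hubs lowers the threshold monotonically in gamma", {
  net <- ba100()
  vals <- sapply(0:4, function(g) {
    cstar_exact(net, rate_profile(net, "power", gamma = -g))$value
  })
  expect_true(all(diff(vals) <= 1e-10))
})

test_that("degree-rate coupling reverses the network ordering of thresholds", {
  ba <- ba100()
  lat <- lattice98()
  expect_gt(cstar_exact(ba, 1)$value, cstar_exact(lat, 1)$value)
  expect_lt(cstar_exact(ba, rate_profile(ba, "power", gamma = -1))$value,
            cstar_exact(lat, rate_profile(lat, "power", gamma = -1))$value)
})
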