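test_that("two connected players fixate the mutant half the time regardless of payoffs", {
  # the first update always copies the other player, so rho = 1/2 exactly in
  # distribution for any b, c, delta and any rates
  est <- simulate_fixation(k2(), c(1, 3), b = 5, c = 1, delta = 0.2,
                           n_runs = 4000, seed = 1)
  expect_lt(abs(est$rho_hat - 0.5), 3 * est$se)
  expect_equal(est$mean_events, 1)
})

test_that("neutral drift calibrates to 1/N", {
  net <- regular100()
  est <- simulate_fixation(net, 1, b = 6, c = 1, delta = 0, n_runs = 2e4,
                           seed = 2)
  expect_lt(abs(est$rho_hat - 1 / 100), 3 * max(est$se, sqrt(0.01 * 0.99 / 2e4)))
})

test_that("the simulator reproduces exact absorption probabilities", {
  lam <- c(1, 1.25, 1.75, 2)
  s4 <- star4()
  grid <- list(c(6, 1, 0.01), c(3, 1, 0.05), c(8, 1, 0))
  for (g in grid) {
    o <- exact_fixation(s4, lam, b = g[1], c = g[2], delta = g[3])
    est <- simulate_fixation(s4, lam, b = g[1], c = g[2], delta = g[3],
                             n_runs = 2e4, seed = 3)
    expect_lt(abs(est$rho_hat - o$rho_C), 3 * max(est$se, 1e-4),
              label = paste("|rho_hat - rho_C| at b/c/delta", paste(g, collapse = "/")))
  }
})

test_that("runs are reproducible per seed and invariant to rate rescaling", {
  net <- regular100()
  a <- simulate_fixation(net, rep(1, 100), b = 6, c = 1, delta = 0.01,
                         n_runs = 2000, seed = 5, collect_stats = TRUE)
  b <- simulate_fixation(net, rep(10, 100), b = 6, c = 1, delta = 0.01,
                         n_runs = 2000, seed = 5, collect_stats = TRUE)
  c <- simulate_fixation(net, rep(1, 100), b = 6, c = 1, delta = 0.01,
                         n_runs = 2000, seed = 6)
  expect_identical(a$rho_hat, b$rho_hat)
  expect_identical(a$mean_events, b$mean_events)
  expect_identical(a$local_stats$Q, b$local_stats$Q)
  expect_false(identical(a$rho_hat, c$rho_hat) &&
                 identical(a$mean_events, c$mean_events))
})

test_that("selection intensities that break fitness positivity are rejected", {
  expect_error(simulate_fixation(k2(), 1, b = 2, c = 1, delta = 1,
                                 n_runs = 10, seed = 1), "delta")
  expect_error(exact_fixation(k2(), 1, b = 2, c = 1, delta = 1.2), "fitness")
})

test_that("a frozen all-cooperator population earns exactly b - c per node", {
  net <- cycle_n(6)
  expect_warning(
    lt <- simulate_longterm(net, 1, b = 5, c = 2, delta = 0.1, u = 0,
                            n_events = 1000, seed = 4, start = "all_C"),
    "frozen"
  )
  expect_equal(lt$mean_payoff, rep(3, 6))
  expect_equal(lt$frac_all_C, 1)
})

test_that("time shared between the absorbing states tracks the fixation ratio", {
  s4 <- star4()
  o <- exact_fixation(s4, 1, b = 8, c = 1, delta = 0.05)
  lt <- simulate_longterm(s4, 1, b = 8, c = 1, delta = 0.05, u = 0.005,
                          n_events = 4e6, seed = 9)
  expect_lt(abs(lt$frac_all_C / (lt$frac_all_C + lt$frac_all_D) -
                  o$rho_C / (o$rho_C + o$rho_D)), 0.02)
})

test_that("slow hub updating raises long-term payoffs on scale-free networks", {
  ba <- ba100()
  pays <- sapply(c(-1, 0, 1), function(g) {
    simulate_longterm(ba, rate_profile(ba, "power", gamma = g), b = 6, c = 1,
                      delta = 0.01, u = 1, n_events = 2e6, seed = 5)$overall
  })
  expect_gt(pays[1], pays[2])  # lambda = 1/k beats identical
  expect_gt(pays[2], pays[3])  # identical beats lambda = k
})

test_that("the neutral pair statistic matches its finite-population value", {
  # on a k-regular graph of size N the competition statistic equals
  # <k>/C*(N) = (N - 2k)/(N - 2), which approaches the pair-approximation
  # value 1 as N grows
  reg50 <- generate_network("random_regular", N = 50, params = list(k = 6),
                            seed = 3)
  q50 <- measure_Q(reg50, 1, delta = 0, n_runs = 4000, seed = 11)
  expect_lt(abs(q50$Q - (50 - 12) / (50 - 2)), 0.05)

  reg300 <- generate_network("random_regular", N = 300, params = list(k = 6),
                             seed = 3)
  q300 <- measure_Q(reg300, 1, delta = 0, n_runs = 700, seed = 11)
  expect_lt(abs(q300$Q - (300 - 12) / (300 - 2)), 0.05)
  expect_gt(q300$Q, q50$Q)  # converging upward towards 1
})

test_that("rate-degree coupling orders the pair statistic", {
  ba <- ba100()
  qs <- sapply(c(-1, 0, 1), function(g) {
    measure_Q(ba, rate_profile(ba, "power", gamma = g), delta = 0.01,
              n_runs = 3000, seed = 5)$Q
  })
  expect_gt(qs[1], qs[2])  # slow hubs surround cooperators with cooperators
  expect_gt(qs[2], qs[3])  # fast hubs erode the cooperator surplus
})

test_that("local statistics come with a per-degree breakdown", {
  ba <- ba100()
  q <- measure_Q(ba, 1, delta = 0, n_runs = 500, seed = 8)
  cls <- q$degree_classes
  expect_true(nrow(cls) > 1)
  expect_true(all(cls[, "q_CC"] >= 0 & cls[, "q_CC"] <= 1, na.rm = TRUE))
  expect_true(all(cls[, "q_CD"] >= 0 & cls[, "q_CD"] <= 1, na.rm = TRUE))
})
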