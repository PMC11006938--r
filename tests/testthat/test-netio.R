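test_that("generators produce the documented degree structure", {
  k3n <- k3()
  expect_equal(nrow(k3n$edges), 3)
  expect_equal(k3n$deg, rep(2, 3))

  ds <- generate_network("double_star", params = list(leaves = 5))
  expect_equal(ds$N, 12)
  expect_equal(sort(ds$deg, decreasing = TRUE)[1:2], c(6, 6))
  expect_equal(sum(ds$deg == 1), 10)

  lat <- lattice98()
  expect_equal(lat$N, 98)
  expect_equal(lat$deg, rep(6, 98))

  ba <- generate_network("scale_free_ba", N = 100, seed = 1)
  expect_lt(abs(ba$mean_degree - 6) / 6, 0.05)

  cy <- cycle_n(6)
  expect_equal(cy$deg, rep(2, 6))
  expect_equal(nrow(cy$edges), 6)
})

test_that("every generated network satisfies the structural invariants", {
  specs <- list(
    list("lattice", NULL, list()),
    list("erdos_renyi", 40, list(mean_degree = 6)),
    list("small_world", 40, list(nei = 3, p = 0.3)),
    list("scale_free_ba", 60, list(m = 3)),
    list("random_regular", 40, list(k = 6)),
    list("configuration", NULL, list(degrees = rep(c(2, 3, 4), c(10, 10, 10)))),
    list("uniform_attachment", 40, list(m = 3)),
    list("double_star", NULL, list(leaves = 4)),
    list("cycle", 9, list()),
    list("complete", 7, list())
  )
  for (sp in specs) {
    net <- generate_network(sp[[1]], N = sp[[2]], params = sp[[3]], seed = 7)
    expect_true(all(net$adj == t(net$adj)), info = sp[[1]])
    expect_true(all(diag(net$adj) == 0), info = sp[[1]])
    expect_true(all(net$deg >= 1), info = sp[[1]])
    expect_equal(net$K, 2 * nrow(net$edges), info = sp[[1]])
    expect_equal(max(coopfix:::connected_components(net$adj)), 1,
                 info = sp[[1]])
  }
})

test_that("generation is deterministic per seed and varies across seeds", {
  a <- generate_network("scale_free_ba", N = 100, seed = 5)
  b <- generate_network("scale_free_ba", N = 100, seed = 5)
  c <- generate_network("scale_free_ba", N = 100, seed = 6)
  expect_identical(a$adj, b$adj)
  expect_false(identical(a$adj, c$adj))
})

test_that("infeasible generator parameters are rejected", {
  expect_error(generate_network("random_regular", N = 5, params = list(k = 3)),
               "infeasible")
  expect_error(generate_network("configuration", params = list(degrees = c(1, 1, 1))),
               "infeasible")
  expect_error(generate_network("double_star", params = list(leaves = 0)))
})

test_that("edge lists are parsed with label mapping and duplicate collapse", {
  net <- path3()
  expect_equal(net$N, 3)
  expect_equal(net$deg, c(1, 2, 1))
  expect_equal(net$labels, c("a", "b", "c"))

  dup <- net_from_lines(c("a b", "a b"))
  expect_equal(dup$N, 2)
  expect_equal(nrow(dup$edges), 1)

  tf <- tempfile()
  writeLines("a a", tf)
  expect_error(read_edge_list(tf), "self-loop")
  writeLines(c("a b", "c d"), tf)
  expect_error(read_edge_list(tf), "disconnected.*components")
  writeLines(c("a b c"), tf)
  expect_error(read_edge_list(tf), "two labels")
  unlink(tf)
})

test_that("edge lists round-trip in both dialects", {
  for (dialect in c("whitespace", "csv")) {
    net <- generate_network("scale_free_ba", N = 30, seed = 2)
    tf <- tempfile()
    write_edge_list(net, tf, dialect = dialect)
    back <- read_edge_list(tf)
    expect_identical(back$adj, net$adj)
    unlink(tf)
  }
  cy <- cycle_n(6)
  tf <- tempfile()
  write_edge_list(cy, tf)
  lines <- readLines(tf)
  expect_length(lines, 6)
  toks <- unlist(strsplit(lines, " "))
  expect_true(all(table(toks) == 2))
  unlink(tf)
})
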