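# small canonical graphs built in code

net_from_lines <- function(lines) {
  tf <- tempfile(fileext = ".edges")
  writeLines(lines, tf)
  on.exit(unlink(tf))
  read_edge_list(tf)
}

k2 <- function() generate_network("complete", N = 2)
k3 <- function() generate_network("complete", N = 3)
path3 <- function() net_from_lines(c("a b", "b c"))
star4 <- function() net_from_lines(c("h a", "h b", "h c"))
cycle_n <- function(n) generate_network("cycle", N = n)

# fixed medium graphs reused across tests
ba100 <- function() generate_network("scale_free_ba", N = 100, seed = 42)
lattice98 <- function() generate_network("lattice")
regular100 <- function() {
  generate_network("random_regular", N = 100, params = list(k = 6), seed = 3)
}

random_connected <- function(N, p = 0.5) {
  repeat {
    adj <- matrix(0, N, N)
    for (i in seq_len(N - 1)) {
      for (j in (i + 1):N) {
        if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1
      }
    }
    ok <- all(rowSums(adj) > 0) &&
      max(coopfix:::connected_components(adj)) == 1
    if (ok) return(coopfix:::new_network(adj, model = "random"))
  }
}

# closed-form critical ratio of a vertex-transitive k-regular graph
regular_cstar <- function(N, k) k * (N - 2) / (N - 2 * k)
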