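#' @title Undirected network container
#'
#' @description Internal constructor for the `coop_network` class: an
#'   undirected, simple, connected graph stored as a dense 0/1 adjacency
#'   matrix with degree bookkeeping. All theory in the package (coalescence
#'   times, critical ratios, the Markov-chain oracle) assumes exactly this
#'   class of graphs.
#'
#' @param adj square 0/1 adjacency matrix.
#' @param labels optional character vector of original node labels.
#' @param model,params,seed provenance metadata recorded on the object.
#' @return object of class `coop_network` with fields `N` (node count),
#'   `adj`, `edges` (two-column matrix, i < j, 1-based), `deg` (per-node
#'   degree `k_i`), `K` (sum of degrees), `mean_degree`, `second_moment`.
#' @keywords internal
new_network <- function(adj, labels = NULL, model = "custom", params = list(),
                        seed = NULL) {
  adj <- unname(as.matrix(adj))
  storage.mode(adj) <- "double"
  validate_adjacency(adj)
  deg <- rowSums(adj)
  edges <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  dimnames(edges) <- NULL
  structure(
    list(
      N = nrow(adj), adj = adj, edges = edges, deg = deg,
      K = sum(deg), mean_degree = mean(deg), second_moment = mean(deg^2),
      labels = labels, model = model, params = params, seed = seed
    ),
    class = "coop_network"
  )
}

validate_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) {
    stop("adjacency must be a square matrix", call. = FALSE)
  }
  if (nrow(adj) < 2) stop("network must have at least 2 nodes", call. = FALSE)
  if (!all(adj %in% c(0, 1))) stop("adjacency entries must be 0/1", call. = FALSE)
  if (any(diag(adj) != 0)) stop("self-loops are not allowed", call. = FALSE)
  if (!isTRUE(all.equal(adj, t(adj)))) stop("adjacency must be symmetric", call. = FALSE)
  if (any(rowSums(adj) < 1)) {
    stop("isolated node: every node needs degree >= 1", call. = FALSE)
  }
  comp <- connected_components(adj)
  if (max(comp) > 1) {
    sizes <- table(comp)
    stop(sprintf("graph is disconnected: %d components of sizes %s",
                 length(sizes), paste(sizes, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# label nodes by connected component (BFS over the adjacency matrix)
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.coop_network <- function(x, ...) {
  cat(sprintf("<coop_network> %s: N = %d, edges = %d, <k> = %.3f, <k^2> = %.3f\n",
              x$model, x$N, nrow(x$edges), x$mean_degree, x$second_moment))
  invisible(x)
}

# evaluate expr with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

igraph_to_network <- function(g, model, params, seed) {
  g <- igraph::simplify(g)
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  adj[adj > 0] <- 1
  new_network(adj, model = model, params = params, seed = seed)
}

# triangular lattice on a torus: every node has exactly six neighbours
triangular_torus <- function(nrow, ncol) {
  if (nrow < 3 || ncol < 3) {
    stop("triangular torus needs at least 3 rows and 3 columns", call. = FALSE)
  }
  id <- function(r, c) ((r - 1) %% nrow) * ncol + ((c - 1) %% ncol) + 1
  N <- nrow * ncol
  adj <- matrix(0, N, N)
  for (r in seq_len(nrow)) {
    for (c in seq_len(ncol)) {
      a <- id(r, c)
      for (b in c(id(r, c + 1), id(r + 1, c), id(r + 1, c + 1))) {
        if (a == b) stop("degenerate lattice dimensions", call. = FALSE)
        adj[a, b] <- 1
        adj[b, a] <- 1
      }
    }
  }
  adj
}

#' Generate a synthetic network
#'
#' Builds the graph families used throughout the package: a degree-6
#' triangular lattice on a torus, Erdos-Renyi, Watts-Strogatz small-world,
#' Barabasi-Albert scale-free, random regular, configuration-model,
#' uniform-attachment, double-star, cycle and complete graphs. Models that do
#' not guarantee connectivity (Erdos-Renyi, configuration, random regular,
#' small-world) are resampled until connected, up to `max_tries` attempts, so
#' generation stays deterministic for a given seed.
#'
#' @param model one of `"lattice"`, `"erdos_renyi"`, `"small_world"`,
#'   `"scale_free_ba"`, `"random_regular"`, `"configuration"`,
#'   `"uniform_attachment"`, `"double_star"`, `"cycle"`, `"complete"`.
#' @param N number of nodes (ignored for `"lattice"`, where `nrow * ncol`
#'   decides, and `"double_star"`, where `2 * leaves + 2` decides).
#' @param params named list of model-specific parameters:
#'   \describe{
#'     \item{lattice}{`nrow`, `ncol` (defaults 7 and 14, i.e. N = 98, k = 6).}
#'     \item{erdos_renyi}{`p` edge probability, or `mean_degree` from which
#'       `p = mean_degree / (N - 1)` (default mean degree 6).}
#'     \item{small_world}{`nei` half-degree of the start ring (default 3) and
#'       rewiring probability `p` (default 0.7).}
#'     \item{scale_free_ba}{`m` edges per incoming node (default 3, giving
#'       mean degree close to 6).}
#'     \item{random_regular}{`k` common degree (default 6); `N * k` must be even.}
#'     \item{configuration}{`degrees` integer degree sequence of length `N`.}
#'     \item{uniform_attachment}{`m` edges per incoming node (default 3).}
#'     \item{double_star}{`leaves` per hub (default 5).}
#'   }
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @param max_tries resampling budget for connectivity (default 1000).
#' @return a [`coop_network`][new_network] object.
#' @examples
#' net <- generate_network("cycle", N = 6)
#' net$deg
#' ba <- generate_network("scale_free_ba", N = 100, seed = 1)
#' ba$mean_degree
#' @export
generate_network <- function(model, N = NULL, params = list(), seed = NULL,
                             max_tries = 1000) {
  model <- match.arg(model, c(
    "lattice", "erdos_renyi", "small_world", "scale_free_ba",
    "random_regular", "configuration", "uniform_attachment",
    "double_star", "cycle", "complete"
  ))
  with_local_seed(seed, {
    net <- switch(model,
      lattice = {
        p <- modifyList(list(nrow = 7, ncol = 14), params)
        new_network(triangular_torus(p$nrow, p$ncol), model = model,
                    params = p, seed = seed)
      },
      cycle = {
        stopifnot(!is.null(N), N >= 3)
        igraph_to_network(igraph::make_ring(N), model, list(N = N), seed)
      },
      complete = {
        stopifnot(!is.null(N), N >= 2)
        igraph_to_network(igraph::make_full_graph(N), model, list(N = N), seed)
      },
      double_star = {
        p <- modifyList(list(leaves = 5), params)
        m <- p$leaves
        if (m < 1) stop("double_star needs at least one leaf per hub", call. = FALSE)
        n <- 2 * m + 2
        adj <- matrix(0, n, n)
        adj[1, 2] <- adj[2, 1] <- 1
        for (l in seq_len(m)) {
          adj[1, 2 + l] <- adj[2 + l, 1] <- 1          # hub 1 leaves
          adj[2, 2 + m + l] <- adj[2 + m + l, 2] <- 1  # hub 2 leaves
        }
        new_network(adj, model = model, params = p, seed = seed)
      },
      scale_free_ba = {
        stopifnot(!is.null(N), N >= 3)
        p <- modifyList(list(m = 3), params)
        igraph_to_network(
          igraph::sample_pa(N, power = 1, m = p$m, directed = FALSE),
          model, p, seed
        )
      },
      uniform_attachment = {
        stopifnot(!is.null(N), N >= 3)
        p <- modifyList(list(m = 3), params)
        retry_connected(max_tries, model, function() {
          igraph::sample_growing(N, m = p$m, directed = FALSE, citation = TRUE)
        }, p, seed)
      },
      erdos_renyi = {
        stopifnot(!is.null(N), N >= 2)
        p <- params
        if (is.null(p$p)) {
          p$mean_degree <- p$mean_degree %||% 6
          p$p <- p$mean_degree / (N - 1)
        }
        retry_connected(max_tries, model, function() {
          igraph::sample_gnp(N, p$p)
        }, p, seed)
      },
      small_world = {
        stopifnot(!is.null(N), N >= 4)
        p <- modifyList(list(nei = 3, p = 0.7), params)
        retry_connected(max_tries, model, function() {
          igraph::sample_smallworld(1, N, nei = p$nei, p = p$p)
        }, p, seed)
      },
      random_regular = {
        stopifnot(!is.null(N))
        p <- modifyList(list(k = 6), params)
        if ((N * p$k) %% 2 != 0 || p$k >= N) {
          stop("infeasible degree for random regular graph: need N*k even and k < N",
               call. = FALSE)
        }
        retry_connected(max_tries, model, function() {
          igraph::sample_k_regular(N, p$k)
        }, p, seed)
      },
      configuration = {
        degs <- params$degrees
        if (is.null(degs)) stop("configuration model needs params$degrees", call. = FALSE)
        if (sum(degs) %% 2 != 0 || any(degs < 1)) {
          stop("infeasible degree sequence", call. = FALSE)
        }
        retry_connected(max_tries, model, function() {
          igraph::sample_degseq(degs, method = "configuration")
        }, params, seed)
      }
    )
    net
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

retry_connected <- function(max_tries, model, gen, params, seed) {
  for (t in seq_len(max_tries)) {
    g <- igraph::simplify(gen())
    if (igraph::vcount(g) >= 2 && igraph::is_connected(g) &&
        min(igraph::degree(g)) >= 1) {
      return(igraph_to_network(g, model, params, seed))
    }
  }
  stop(sprintf("could not generate a connected %s network in %d tries",
               model, max_tries), call. = FALSE)
}

#' Read a network from an edge-list file
#'
#' One edge per line, two node labels per line; labels are arbitrary strings
#' mapped to 1-based indices in first-appearance order, except that a file
#' whose labels are all integers is mapped in numeric order so that written
#' networks round-trip index-identically (the original labels are preserved
#' in `$labels`). Duplicate edges are collapsed; self-loops are rejected; the
#' resulting graph must be connected.
#'
#' @param path file path.
#' @param dialect `"auto"` (default), `"whitespace"` or `"csv"`.
#' @return a [`coop_network`][new_network] object.
#' @export
read_edge_list <- function(path, dialect = c("auto", "whitespace", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty edge list: ", path, call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (grepl(",", lines[[1]], fixed = TRUE)) "csv" else "whitespace"
  }
  toks <- if (dialect == "csv") {
    strsplit(lines, ",", fixed = TRUE)
  } else {
    strsplit(lines, "[[:space:]]+")
  }
  toks <- lapply(toks, function(x) trimws(x[nzchar(trimws(x))]))
  bad <- which(vapply(toks, length, 1L) != 2L)
  if (length(bad)) {
    stop(sprintf("line %d: expected two labels per line", bad[[1]]), call. = FALSE)
  }
  a <- vapply(toks, `[[`, "", 1L)
  b <- vapply(toks, `[[`, "", 2L)
  if (any(a == b)) {
    stop(sprintf("line %d: self-loop '%s'", which(a == b)[[1]], a[a == b][[1]]),
         call. = FALSE)
  }
  labels <- unique(c(rbind(a, b)))
  if (!anyNA(suppressWarnings(as.integer(labels)))) {
    labels <- labels[order(as.integer(labels))]
  }
  n <- length(labels)
  ia <- match(a, labels)
  ib <- match(b, labels)
  adj <- matrix(0, n, n)
  adj[cbind(ia, ib)] <- 1
  adj[cbind(ib, ia)] <- 1
  new_network(adj, labels = labels, model = "file",
              params = list(path = path, dialect = dialect))
}

#' Write a network as an edge-list file
#'
#' Writes one line per edge using the stored node labels (or 1-based indices
#' when no labels are present). Round-trips through [read_edge_list()] to an
#' index-identical graph.
#'
#' @param network a `coop_network`.
#' @param path output file path.
#' @param dialect `"whitespace"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path, dialect = c("whitespace", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(network, "coop_network"))
  labels <- network$labels %||% as.character(seq_len(network$N))
  sep <- if (dialect == "csv") "," else " "
  lines <- paste(labels[network$edges[, 1]], labels[network$edges[, 2]], sep = sep)
  writeLines(lines, path)
  invisible(path)
}
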