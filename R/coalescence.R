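#' Random-walk step matrices
#'
#' One-, two- and three-step random-walk probability matrices of a network:
#' `p[i, j] = e_ij / k_i`, with the higher orders obtained by composition.
#'
#' @param network a `coop_network`.
#' @return object of class `walk_operators`: list with `p`, `p2`, `p3`.
#' @export
step_matrices <- function(network) {
  stopifnot(inherits(network, "coop_network"))
  p <- network$adj / network$deg
  p2 <- p %*% p
  structure(list(p = p, p2 = p2, p3 = p2 %*% p), class = "walk_operators")
}

#' Per-node update-rate profile
#'
#' Builds the vector of personalised update rates \eqn{\lambda_i} used by the
#' evolutionary process: node `i` is selected to revise its strategy with
#' probability \eqn{\lambda_i / \Lambda} per event, \eqn{\Lambda = \sum_i
#' \lambda_i}. Only rate ratios matter for every quantity in the package.
#'
#' @param network a `coop_network`.
#' @param scheme one of:
#'   \describe{
#'     \item{`"identical"`}{\eqn{\lambda_i = 1} (the canonical death-birth model).}
#'     \item{`"power"`}{\eqn{\lambda_i = k_i^\gamma}; pass `gamma` (may be
#'       negative, e.g. `gamma = -1` for rates inversely proportional to degree).}
#'     \item{`"uniform"`}{i.i.d. Uniform(`min`, `max`), defaults 0.5 and 1.5.}
#'     \item{`"normal"`}{i.i.d. Normal(`mean`, `sd`), defaults 1 and 0.25,
#'       truncated below at `floor` (default 0.05) by resampling.}
#'     \item{`"exponential"`}{i.i.d. Exponential with `mean` (default 1).}
#'     \item{`"power_law"`}{Pareto with tail exponent `alpha` (default 2.5)
#'       and minimum `xmin` (default 0.1).}
#'   }
#' @param gamma exponent for the `"power"` scheme (default 1).
#' @param params named list overriding the distribution defaults above.
#' @param seed integer seed for the sampled schemes (draws are deterministic
#'   given the seed).
#' @return object of class `rate_profile`: list with `lambda` (positive,
#'   length N), `Lambda`, `scheme` and the resolved `params`.
#' @examples
#' net <- generate_network("double_star", params = list(leaves = 5))
#' rate_profile(net, "power", gamma = -1)$lambda
#' @export
rate_profile <- function(network, scheme = c("identical", "power", "uniform",
                                             "normal", "exponential", "power_law"),
                         gamma = 1, params = list(), seed = NULL) {
  stopifnot(inherits(network, "coop_network"))
  scheme <- match.arg(scheme)
  N <- network$N
  lam <- with_local_seed(seed, switch(scheme,
    identical = rep(1, N),
    power = network$deg^gamma,
    uniform = {
      p <- modifyList(list(min = 0.5, max = 1.5), params)
      if (p$min <= 0 || p$max <= p$min) stop("need 0 < min < max", call. = FALSE)
      runif(N, p$min, p$max)
    },
    normal = {
      p <- modifyList(list(mean = 1, sd = 0.25, floor = 0.05), params)
      if (p$sd <= 0 || p$floor <= 0) stop("need sd > 0 and floor > 0", call. = FALSE)
      x <- rnorm(N, p$mean, p$sd)
      while (any(x < p$floor)) {
        x[x < p$floor] <- rnorm(sum(x < p$floor), p$mean, p$sd)
      }
      x
    },
    exponential = {
      p <- modifyList(list(mean = 1), params)
      if (p$mean <= 0) stop("need mean > 0", call. = FALSE)
      rexp(N, rate = 1 / p$mean)
    },
    power_law = {
      p <- modifyList(list(alpha = 2.5, xmin = 0.1), params)
      if (p$alpha <= 1 || p$xmin <= 0) stop("need alpha > 1 and xmin > 0", call. = FALSE)
      p$xmin * runif(N)^(-1 / (p$alpha - 1))
    }
  ))
  new_rate_profile(lam, scheme = scheme,
                   params = if (scheme == "power") list(gamma = gamma) else params,
                   seed = seed)
}

#' @rdname rate_profile
#' @param lambda explicit positive rate vector (length N of the target network).
#' @param ... metadata stored on the object.
#' @export
new_rate_profile <- function(lambda, ...) {
  lambda <- as.numeric(lambda)
  if (!length(lambda) || any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("update rates must be positive and finite", call. = FALSE)
  }
  structure(list(lambda = lambda, Lambda = sum(lambda), ...),
            class = "rate_profile")
}

#' @export
print.rate_profile <- function(x, ...) {
  cat(sprintf("<rate_profile> %s: N = %d, Lambda = %.4g, range [%.4g, %.4g]\n",
              x$scheme %||% "custom", length(x$lambda), x$Lambda,
              min(x$lambda), max(x$lambda)))
  invisible(x)
}

as_rates <- function(rates, network) {
  if (inherits(rates, "rate_profile")) {
    lam <- rates$lambda
  } else {
    lam <- as.numeric(rates)
  }
  if (length(lam) == 1) lam <- rep(lam, network$N)
  if (length(lam) != network$N) {
    stop("rate profile length does not match the network", call. = FALSE)
  }
  if (any(!is.finite(lam)) || any(lam <= 0)) {
    stop("update rates must be positive and finite", call. = FALSE)
  }
  lam
}

#' Pairwise coalescence times of rate-weighted random walks
#'
#' Solves the linear recurrence for the expected meeting time
#' \eqn{\eta_{ij}} of two random walkers started at nodes i and j, where at
#' each event the walker at i moves with probability
#' \eqn{\lambda_i / (\lambda_i + \lambda_j)}:
#' \deqn{\eta_{ij} = \frac{\Lambda}{N(\lambda_i+\lambda_j)}
#'   + \sum_k \frac{\lambda_i}{\lambda_i+\lambda_j} p_{ik}\eta_{kj}
#'   + \sum_k \frac{\lambda_j}{\lambda_i+\lambda_j} p_{jk}\eta_{ki}, \quad
#'   \eta_{ii} = 0.}
#' These meeting times are the neutral-drift backbone of the critical
#' benefit-to-cost ratio.
#'
#' Three solvers are available. `"pairs"` (the default) assembles the
#' \eqn{N(N-1)/2}-unknown pair system as a sparse symmetric positive-definite
#' matrix (a diagonal row scaling by \eqn{1/(s_i s_j)}, \eqn{s_i =
#' \lambda_i/k_i}, symmetrises the operator) and applies a sparse Cholesky
#' factorisation; the solution stays accurate to machine precision even when
#' rates span many orders of magnitude, as they do along an optimisation
#' trajectory, and the same factorisation is what the update-rate optimiser
#' reuses for its derivative systems. `"eigen"` rewrites the recurrence as a Lyapunov equation
#' \eqn{A\eta + \eta A^T = (\Lambda/N)(J-I) + \mathrm{diag}(\phi)} with
#' unknown diagonal sources \eqn{\phi} enforcing \eqn{\eta_{ii}=0}, where
#' \eqn{A = D_\lambda (I - P)} is diagonalised through its symmetrisation by
#' \eqn{S^{1/2}}, \eqn{S = \mathrm{diag}(\lambda_i / k_i)}; this is exact at
#' \eqn{O(N^3)} cost and fast for moderate rate spreads. `"fixed_point"`
#' iterates the recurrence (Jacobi) until the sup-norm change is below
#' `tol_fp`.
#'
#' @param network a `coop_network`.
#' @param rates a `rate_profile`, a positive numeric vector, or a scalar.
#' @param method `"pairs"` (default), `"eigen"` or `"fixed_point"`.
#' @param tol residual acceptance threshold for the direct methods
#'   (default 1e-10).
#' @param tol_fp convergence threshold for the fixed-point iteration
#'   (default 1e-12 on the sup-norm step; residual accepted at 1e-8).
#' @param max_iter_fp iteration cap for the fixed-point method.
#' @return object of class `coalescence_table`: list with the symmetric
#'   matrix `eta` (zero diagonal), the achieved `residual` (max absolute
#'   violation of the recurrence in its natural form; accepted when below the
#'   tolerance scaled by the magnitude of eta), `method`, and `eta_bar`
#'   (mean of \eqn{\eta_{ij}} over unordered pairs).
#' @examples
#' net <- generate_network("complete", N = 3)
#' solve_coalescence(net, rate_profile(net, "identical"))$eta
#' @export
solve_coalescence <- function(network, rates,
                              method = c("pairs", "eigen", "fixed_point"),
                              tol = 1e-10, tol_fp = 1e-12, max_iter_fp = 1e6) {
  stopifnot(inherits(network, "coop_network"))
  method <- match.arg(method)
  lam <- as_rates(rates, network)
  eta <- switch(method,
    pairs = {
      ps <- pair_system(network, lam)
      eta_from_pairs(ps, as.numeric(Matrix::solve(pair_factor(ps), ps$rhs)),
                     network$N)
    },
    eigen = {
      cache <- lyap_cache(network, lam)
      R0 <- matrix(sum(lam) / network$N, network$N, network$N)
      diag(R0) <- 0
      lyap_solve_refined(cache, R0, network, lam)
    },
    fixed_point = solve_eta_fixed_point(network, lam, tol_fp, max_iter_fp)
  )
  res <- eta_residual(network, lam, eta)
  accept <- (if (method == "fixed_point") 1e-8 else tol) * max(1, max(abs(eta)))
  if (!is.finite(res) || res > accept) {
    stop(sprintf(
      "coalescence solve (%s) residual %.3e exceeds %.1e; the network may be ill-conditioned",
      method, res, accept
    ), call. = FALSE)
  }
  structure(
    list(eta = eta, residual = res, method = method,
         eta_bar = sum(eta[upper.tri(eta)]) / (network$N * (network$N - 1) / 2)),
    class = "coalescence_table"
  )
}

#' @export
print.coalescence_table <- function(x, ...) {
  cat(sprintf("<coalescence_table> N = %d, eta_bar = %.6g, residual = %.2e (%s)\n",
              nrow(x$eta), x$eta_bar, x$residual, x$method))
  invisible(x)
}

# off-diagonal defect of the recurrence multiplied through by
# lambda_i + lambda_j: RHS - [(lam_i+lam_j) eta_ij - lam_i (P eta)_ij
#                             - lam_j (P eta)_ji]
eta_defect <- function(network, lam, eta, rhs) {
  P <- network$adj / network$deg
  Pe <- P %*% eta
  R <- rhs - (outer(lam, lam, "+") * eta - lam * Pe - t(lam * Pe))
  diag(R) <- 0
  R
}

# max absolute violation of the coalescence recurrence in its natural form
# (units of eta)
eta_residual <- function(network, lam, eta) {
  rhs <- matrix(sum(lam) / network$N, network$N, network$N)
  D <- eta_defect(network, lam, eta, rhs)
  max(abs(D / outer(lam, lam, "+")))
}

# eigen solve plus iterative refinement on the defect; refinement reuses the
# cached decomposition, so each pass costs a handful of matrix products
lyap_solve_refined <- function(cache, R0, network, lam, passes = 2) {
  eta <- lyap_solve(cache, R0)
  for (p in seq_len(passes)) {
    D <- eta_defect(network, lam, eta, R0)
    if (max(abs(D)) <= 1e-13 * max(1, max(abs(R0)))) break
    eta <- eta + lyap_solve(cache, D)
  }
  eta
}

# eigendecomposition cache for the Lyapunov operator eta -> A eta + eta A^T,
# A = D_lambda (I - P), including the factorised map from diagonal sources to
# the solution diagonal (used to enforce eta_ii = 0)
lyap_cache <- function(network, lam) {
  N <- network$N
  deg <- network$deg
  sh <- sqrt(lam / deg)
  Lg <- diag(deg) - network$adj
  ee <- eigen(sh * t(sh * Lg), symmetric = TRUE)
  V <- ee$vectors
  mu <- ee$values
  W <- sh * V                 # A = W diag(mu) W^{-1}
  Winv <- t(V / sh)
  denom <- outer(mu, mu, "+")
  z <- N                      # eigenvalues sorted decreasing; mu[N] = 0 mode
  denom[z, z] <- 1            # guarded; the (z,z) component is handled separately
  # H[i, m]: diagonal of the particular solution driven by a unit source at m
  H <- matrix(0, N, N)
  for (m in seq_len(N)) {
    xim <- outer(Winv[, m], Winv[, m]) / denom
    xim[z, z] <- 0
    H[, m] <- rowSums((W %*% xim) * W)
  }
  wz <- W[, z]
  Amat <- rbind(cbind(H, wz^2), c(Winv[z, ]^2, 0))
  list(N = N, W = W, Winv = Winv, denom = denom, z = z, wz = wz,
       qr = qr(Amat))
}

# solve A eta + eta A^T = R0 + diag(phi) with eta symmetric, diag(eta) = 0;
# R0 symmetric with arbitrary off-diagonal entries (its diagonal is ignored)
lyap_solve <- function(cache, R0) {
  diag(R0) <- 0
  z <- cache$z
  G0 <- cache$Winv %*% R0 %*% t(cache$Winv)
  xi0 <- G0 / cache$denom
  xi0[z, z] <- 0
  eta0 <- cache$W %*% xi0 %*% t(cache$W)
  sol <- qr.coef(cache$qr, c(-diag(eta0), -G0[z, z]))
  phi <- sol[seq_len(cache$N)]
  Gp <- cache$Winv %*% (phi * t(cache$Winv))   # Winv %*% diag(phi) %*% t(Winv)
  xip <- Gp / cache$denom
  xip[z, z] <- 0
  eta <- eta0 + cache$W %*% xip %*% t(cache$W) +
    sol[cache$N + 1] * outer(cache$wz, cache$wz)
  eta <- (eta + t(eta)) / 2
  diag(eta) <- 0
  eta
}

# Sparse symmetric assembly of the pair system. The recurrence multiplied
# through by s_ij = lambda_i + lambda_j reads, for each unordered pair {i, j},
#   s_ij eta_ij - lambda_i sum_k p_ik eta_kj - lambda_j sum_k p_jk eta_ki
#     = Lambda / N
# (eta_ii = eta_jj = 0 terms dropped). Scaling the {i, j} row by
# w_ij = 1 / (s_i s_j), s_i = lambda_i / k_i, symmetrises the operator: the
# coupling of pair {i, j} to {k, j} along an edge (i, k) becomes 1/s_j on
# both sides. The symmetrised matrix is irreducibly diagonally dominant with
# positive diagonal, hence positive definite, so a sparse Cholesky
# factorisation applies; it stays accurate even when rates span many orders
# of magnitude, as they do along an optimisation trajectory.
pair_system <- function(network, lam) {
  N <- network$N
  P <- network$adj / network$deg
  pr <- which(upper.tri(diag(N)), arr.ind = TRUE)
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  M <- nrow(pr)
  idx <- matrix(0L, N, N)
  idx[pr] <- seq_len(M)
  idx[pr[, c(2, 1), drop = FALSE]] <- seq_len(M)
  rows <- cols <- vals <- vector("list", N)
  for (i in seq_len(N)) {
    js <- setdiff(seq_len(N), i)
    nbk <- which(network$adj[i, ] > 0)
    j_rep <- rep(js, each = length(nbk))
    k_rep <- rep(nbk, times = length(js))
    keep <- k_rep != j_rep
    j_rep <- j_rep[keep]
    k_rep <- k_rep[keep]
    if (!length(j_rep)) next
    rows[[i]] <- idx[cbind(rep.int(i, length(j_rep)), j_rep)]
    cols[[i]] <- idx[cbind(k_rep, j_rep)]
    vals[[i]] <- -lam[i] * P[cbind(rep.int(i, length(k_rep)), k_rep)]
  }
  ri <- as.integer(unlist(rows))
  D <- Matrix::Diagonal(M, lam[pr[, 1]] + lam[pr[, 2]])
  A <- if (length(ri)) {
    Matrix::sparseMatrix(i = ri, j = as.integer(unlist(cols)),
                         x = as.numeric(unlist(vals)), dims = c(M, M)) + D
  } else {
    D  # a single edge: the one pair equation has no off-diagonal coupling
  }
  s_node <- lam / network$deg
  w <- 1 / (s_node[pr[, 1]] * s_node[pr[, 2]])
  WA <- Matrix::Diagonal(M, w) %*% A
  S <- Matrix::forceSymmetric((WA + Matrix::t(WA)) / 2)
  list(S = S, w = w, rhs = w * sum(lam) / N, pairs = pr, idx = idx,
       s = lam[pr[, 1]] + lam[pr[, 2]], M = M)
}

pair_factor <- function(ps) {
  tryCatch(
    Matrix::Cholesky(ps$S, LDL = FALSE, super = TRUE, perm = TRUE),
    error = function(e) Matrix::Cholesky(ps$S, LDL = TRUE, perm = TRUE)
  )
}

eta_from_pairs <- function(ps, x, N) {
  eta <- matrix(0, N, N)
  eta[ps$pairs] <- x
  eta[ps$pairs[, c(2, 1), drop = FALSE]] <- x
  eta
}

# Independent dense assembly of the identical-rate reduction
#   eta_ij = 1/2 + (1/2) sum_k p_ik eta_kj + (1/2) sum_k p_jk eta_ki
# (the constant Lambda/(N(lambda_i+lambda_j)) is scale invariant and equals
# 1/2 whenever all rates agree); used as a cross-check of the general solver
# at lambda = 1 (tests only)
solve_eta_identical <- function(network) {
  N <- network$N
  P <- network$adj / network$deg
  pr <- which(upper.tri(diag(N)), arr.ind = TRUE)
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  M <- nrow(pr)
  idx <- matrix(0L, N, N)
  idx[pr] <- seq_len(M)
  idx[pr[, c(2, 1), drop = FALSE]] <- seq_len(M)
  A <- diag(M)
  for (m in seq_len(M)) {
    i <- pr[m, 1]
    j <- pr[m, 2]
    for (k in which(network$adj[i, ] > 0)) {
      if (k != j) A[m, idx[k, j]] <- A[m, idx[k, j]] - P[i, k] / 2
    }
    for (k in which(network$adj[j, ] > 0)) {
      if (k != i) A[m, idx[k, i]] <- A[m, idx[k, i]] - P[j, k] / 2
    }
  }
  eta_from_pairs(list(pairs = pr), solve(A, rep(1 / 2, M)), N)
}

# Jacobi iteration of the recurrence itself
solve_eta_fixed_point <- function(network, lam, tol_fp, max_iter) {
  N <- network$N
  P <- network$adj / network$deg
  S <- outer(lam, lam, "+")
  const <- sum(lam) / (N * S)
  eta <- matrix(0, N, N)
  for (it in seq_len(max_iter)) {
    Pe <- P %*% eta
    new <- const + (lam * Pe + t(lam * Pe)) / S
    diag(new) <- 0
    step <- max(abs(new - eta))
    eta <- new
    if (step < tol_fp) return(eta)
  }
  warning("fixed-point coalescence solve hit max_iter before tolerance")
  eta
}

#' Reproductive values under neutral drift
#'
#' The reproductive value \eqn{\pi_i \propto k_i / \lambda_i} quantifies the
#' expected contribution of node i to the future gene pool under neutral
#' drift; nodes that update rarely (small \eqn{\lambda_i}) and are copied
#' often (large \eqn{k_i}) carry more weight. Normalised so that
#' \eqn{\sum_i \pi_i = 1}; the weighted cooperator frequency
#' \eqn{\hat x = \sum_i \pi_i x_i} is then a martingale of the neutral process.
#'
#' @inheritParams solve_coalescence
#' @return object of class `reproductive_values`: list with `pi`.
#' @export
reproductive_values <- function(network, rates) {
  stopifnot(inherits(network, "coop_network"))
  lam <- as_rates(rates, network)
  w <- network$deg / lam
  structure(list(pi = w / sum(w)), class = "reproductive_values")
}
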