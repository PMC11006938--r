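# Exact finite-state computations for small networks: the full evolutionary
# process on N nodes is an absorbing Markov chain over the 2^N strategy
# configurations, with all-cooperator and all-defector states absorbing.
# These brute-force results are the package's ground truth for the simulator
# and the weak-selection theory.

oracle_cap_check <- function(network, max_N) {
  if (network$N > max_N) {
    stop(sprintf("exact chain limited to N <= %d (2^N states); got N = %d",
                 max_N, network$N), call. = FALSE)
  }
}

# all 2^N strategy vectors as an S x N 0/1 matrix (state s = bitmask s - 1)
state_matrix <- function(N) {
  s <- 0:(2^N - 1)
  m <- matrix(0L, length(s), N)
  for (i in seq_len(N)) m[, i] <- bitwAnd(bitwShiftR(s, i - 1L), 1L)
  m
}

# transition kernel T(delta) and its analytic derivative dT/ddelta at delta = 0.
# Transitions: updater i with prob lambda_i/Lambda copies neighbour j with
# prob e_ij F_j / sum_l e_il F_l, F_j = 1 + delta f_j,
# f_j = -c x_j + b (P x)_j.
build_kernel <- function(network, lam, b, c, delta, derivative = FALSE) {
  N <- network$N
  adj <- network$adj
  P <- adj / network$deg
  lamw <- lam / sum(lam)
  X <- state_matrix(N)
  S <- nrow(X)
  Tm <- matrix(0, S, S)
  Dm <- if (derivative) matrix(0, S, S) else NULL
  pow2 <- 2^(0:(N - 1))
  for (s in seq_len(S)) {
    x <- X[s, ]
    f <- -c * x + b * as.vector(P %*% x)
    F <- 1 + delta * f
    if (any(F <= 0)) {
      stop("selection too strong: nonpositive fitness (need delta * c < 1)",
           call. = FALSE)
    }
    Pf <- as.vector(P %*% f)
    for (i in seq_len(N)) {
      nb <- which(adj[i, ] > 0)
      w <- F[nb]
      w <- w / sum(w)
      targets <- s + (x[nb] - x[i]) * pow2[i]
      for (t in seq_along(nb)) {
        Tm[s, targets[t]] <- Tm[s, targets[t]] + lamw[i] * w[t]
        if (derivative) {
          # d/ddelta of w at delta = 0: p_ij (f_j - (P f)_i) per neighbour j
          dw <- P[i, nb[t]] * (f[nb[t]] - Pf[i])
          Dm[s, targets[t]] <- Dm[s, targets[t]] + lamw[i] * dw
        }
      }
    }
  }
  list(Tm = Tm, Dm = Dm, X = X)
}

#' Exact fixation probabilities by full Markov-chain enumeration
#'
#' Builds the complete transition kernel of the evolutionary process over all
#' \eqn{2^N} strategy configurations and solves the absorption system
#' exactly. Serves as the brute-force oracle for the Monte-Carlo engine and
#' the weak-selection formulas on small networks.
#'
#' @inheritParams rho_c_weak_selection
#' @param max_N hard size cap (default 12).
#' @return object of class `oracle_result`: `rho_C` and `rho_D` (absorption
#'   probabilities averaged over uniform single-mutant starts), `h` (fixation
#'   probability of cooperation from every single-cooperator start), and
#'   `completeness` (max deviation of C- plus D-absorption from 1).
#' @examples
#' k2 <- generate_network("complete", N = 2)
#' exact_fixation(k2, c(1, 3), b = 2, c = 1, delta = 0)$h  # 3/4 from node 1
#' @export
exact_fixation <- function(network, rates, b, c, delta, max_N = 12) {
  stopifnot(inherits(network, "coop_network"), delta >= 0)
  oracle_cap_check(network, max_N)
  lam <- as_rates(rates, network)
  N <- network$N
  kern <- build_kernel(network, lam, b, c, delta)
  S <- 2^N
  allD <- 1L
  allC <- S
  trans <- setdiff(seq_len(S), c(allD, allC))
  Q <- kern$Tm[trans, trans]
  IQ <- diag(length(trans)) - Q
  hC <- solve(IQ, kern$Tm[trans, allC])
  hD <- solve(IQ, kern$Tm[trans, allD])
  completeness <- max(abs(hC + hD - 1))
  h_full <- numeric(S)
  h_full[allC] <- 1
  h_full[trans] <- hC
  pow2 <- 2^(0:(N - 1))
  starts_C <- pow2 + 1L           # single cooperator at node i
  starts_D <- (S - 1L) - pow2 + 1L  # single defector at node i
  structure(
    list(
      rho_C = mean(h_full[starts_C]),
      rho_D = mean(1 - h_full[starts_D]),
      h = h_full[starts_C],
      completeness = completeness
    ),
    class = "oracle_result"
  )
}

#' @export
print.oracle_result <- function(x, ...) {
  cat(sprintf("<oracle_result> rho_C = %.6g, rho_D = %.6g\n", x$rho_C, x$rho_D))
  invisible(x)
}

#' Analytic derivative of the fixation probability at zero selection
#'
#' Differentiates the absorption linear system of the exact chain in the
#' selection intensity at \eqn{\delta = 0}: with \eqn{(I - Q)h = a},
#' \eqn{(I - Q_0)h' = Q_0' h_0 + a_0'}, where the kernel derivative is
#' analytic (each fitness is affine in \eqn{\delta}). Optionally cross-checks
#' against a central finite difference.
#'
#' @inheritParams exact_fixation
#' @param fd_check when `TRUE`, also computes the central finite difference
#'   at `fd_h` and errors if the relative disagreement exceeds `fd_tol`.
#' @param fd_h,fd_tol finite-difference step (default 1e-4) and acceptance
#'   (default 1e-6 relative).
#' @return \eqn{d\rho_C/d\delta} at \eqn{\delta = 0} (scalar). Cooperation is
#'   favoured at this (b, c) when the derivative is positive.
#' @export
weak_selection_derivative <- function(network, rates, b, c, max_N = 12,
                                      fd_check = FALSE, fd_h = 1e-4,
                                      fd_tol = 1e-6) {
  stopifnot(inherits(network, "coop_network"))
  oracle_cap_check(network, max_N)
  lam <- as_rates(rates, network)
  d <- oracle_derivative_core(network, lam, b, c)
  if (fd_check) {
    # centred difference around 0: negative delta means fitness 1 - h f,
    # which build_kernel handles directly
    rp <- exact_fixation(network, lam, b, c, fd_h, max_N)$rho_C
    rmm <- exact_fixation_signed(network, lam, b, c, -fd_h, max_N)
    fd <- (rp - rmm) / (2 * fd_h)
    if (abs(fd - d) > fd_tol * max(abs(d), 1e-12)) {
      stop(sprintf("finite-difference cross-check failed: analytic %.10g vs FD %.10g",
                   d, fd), call. = FALSE)
    }
  }
  d
}

# exact chain evaluated at a (possibly negative) delta, used only for the
# centred finite-difference cross-check
exact_fixation_signed <- function(network, lam, b, c, delta, max_N) {
  kern <- build_kernel(network, lam, b, c, delta)
  N <- network$N
  S <- 2^N
  trans <- setdiff(seq_len(S), c(1L, S))
  hC <- solve(diag(length(trans)) - kern$Tm[trans, trans], kern$Tm[trans, S])
  pow2 <- 2^(0:(N - 1))
  h_full <- numeric(S)
  h_full[S] <- 1
  h_full[trans] <- hC
  mean(h_full[pow2 + 1L])
}

oracle_derivative_core <- function(network, lam, b, c) {
  kern <- build_kernel(network, lam, b, c, 0, derivative = TRUE)
  N <- network$N
  S <- 2^N
  trans <- setdiff(seq_len(S), c(1L, S))
  IQ <- diag(length(trans)) - kern$Tm[trans, trans]
  h0 <- numeric(S)
  h0[S] <- 1
  h0[trans] <- solve(IQ, kern$Tm[trans, S])
  rhs <- as.vector(kern$Dm[trans, ] %*% h0)
  hprime <- solve(IQ, rhs)
  pow2 <- 2^(0:(N - 1))
  starts <- pow2 + 1L
  idx <- match(starts, trans)
  mean(hprime[idx])
}

#' Empirical critical ratio from the exact chain
#'
#' Operationalises the definition of the critical benefit-to-cost ratio:
#' fixes c = 1 and bisects the benefit b for the sign change of the analytic
#' weak-selection derivative of the exact chain. Reports `never_favoured`
#' when the derivative stays negative up to `b_max` and `divergent` when it
#' is positive throughout.
#'
#' @inheritParams exact_fixation
#' @param b_max bisection upper bound (default `10 * N`).
#' @param tol absolute tolerance on the bisected b (default 1e-8).
#' @return list with `value` (the critical b at c = 1, or `NA`), `regime`
#'   (`"finite_positive"`, `"never_favoured"` or `"divergent"`).
#' @export
empirical_cstar <- function(network, rates, b_max = NULL, tol = 1e-8,
                            max_N = 12) {
  stopifnot(inherits(network, "coop_network"))
  oracle_cap_check(network, max_N)
  lam <- as_rates(rates, network)
  N <- network$N
  b_max <- b_max %||% (10 * N)
  b_lo <- tol
  d_lo <- oracle_derivative_core(network, lam, b_lo, 1)
  d_hi <- oracle_derivative_core(network, lam, b_max, 1)
  if (d_hi < 0) {
    return(list(value = NA_real_, regime = "never_favoured"))
  }
  if (d_lo > 0) {
    return(list(value = NA_real_, regime = "divergent"))
  }
  lo <- b_lo
  hi <- b_max
  while (hi - lo > tol * max(1, lo)) {
    mid <- (lo + hi) / 2
    if (oracle_derivative_core(network, lam, mid, 1) > 0) hi <- mid else lo <- mid
  }
  list(value = (lo + hi) / 2, regime = "finite_positive")
}
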