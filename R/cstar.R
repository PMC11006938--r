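#' @title Critical benefit-to-cost ratio results
#' @description Container for the critical ratio \eqn{C^*} above which
#'   selection favours the fixation of cooperation. `regime` is
#'   `"finite_positive"` when the denominator of the defining ratio is
#'   positive, `"never_favoured"` when it is negative (no finite benefit can
#'   favour cooperation; complete graphs are the canonical example), and
#'   `"divergent"` when it vanishes.
#' @keywords internal
new_cstar_result <- function(value, numerator, denominator, method,
                             components = list()) {
  tolz <- 1e-12 * max(abs(numerator), 1)
  regime <- if (abs(denominator) <= tolz) {
    "divergent"
  } else if (denominator < 0) {
    "never_favoured"
  } else {
    "finite_positive"
  }
  structure(
    list(
      value = if (abs(denominator) > tolz) value else NA_real_,
      regime = regime, numerator = numerator, denominator = denominator,
      method = method, components = components
    ),
    class = "cstar_result"
  )
}

#' @export
print.cstar_result <- function(x, ...) {
  cat(sprintf("<cstar_result> method = %s, regime = %s\n", x$method, x$regime))
  if (is.finite(x$value %||% NA)) cat(sprintf("  C* = %.6g\n", x$value))
  cat(sprintf("  numerator = %.6g, denominator = %.6g\n",
              x$numerator, x$denominator))
  invisible(x)
}

# the three eta-weighted walk sums entering the critical ratio:
# S_n = sum_{i,j} k_i p^(n)_ij eta_ij (ordered sums; diagonal terms vanish)
walk_sums <- function(network, eta, ops = NULL) {
  ops <- ops %||% step_matrices(network)
  k <- network$deg
  c(
    s1 = sum(k * ops$p * eta),
    s2 = sum(k * ops$p2 * eta),
    s3 = sum(k * ops$p3 * eta)
  )
}

#' Exact critical benefit-to-cost ratio
#'
#' Computes
#' \deqn{C^* = \frac{\sum_{i,j} k_i p^{(2)}_{ij}\eta_{ij}}
#'   {\sum_{i,j} k_i p^{(3)}_{ij}\eta_{ij} - \sum_{i,j} k_i p_{ij}\eta_{ij}}}
#' from the coalescence times \eqn{\eta_{ij}} of [solve_coalescence()].
#' Cooperation fixates with probability above the neutral 1/N (to first order
#' in the selection intensity) exactly when b/c exceeds this ratio.
#'
#' @inheritParams solve_coalescence
#' @param solver passed to [solve_coalescence()] as `method`.
#' @return a `cstar_result`; `components` carries `eta_bar`, the per-order
#'   sums `eta_n = ` \eqn{\eta^{(n)} = \sum_{i,j} k_i p^{(n)}_{ij}\eta_{ij}/K}
#'   for n = 1..3, and the solver residual.
#' @examples
#' k3 <- generate_network("complete", N = 3)
#' cstar_exact(k3, 1)            # C* = -2: spite, cooperation never favoured
#' cy <- generate_network("cycle", N = 6)
#' cstar_exact(cy, 1)$value      # 4, the regular-graph value k(N-2)/(N-2k)
#' @export
cstar_exact <- function(network, rates, solver = "pairs") {
  stopifnot(inherits(network, "coop_network"))
  ct <- solve_coalescence(network, rates, method = solver)
  ops <- step_matrices(network)
  s <- walk_sums(network, ct$eta, ops)
  num <- s[["s2"]]
  den <- s[["s3"]] - s[["s1"]]
  new_cstar_result(num / den, num, den, "exact", components = list(
    eta_bar = ct$eta_bar,
    eta_n = s / network$K,
    residual = ct$residual
  ))
}

# exact O(N^2)-O(N^3) building blocks of the mean-field expansion
approx_blocks <- function(network, lam, ops) {
  N <- network$N
  k <- network$deg
  K <- network$K
  Lam <- sum(lam)
  S <- outer(lam, lam, "+")
  zeta <- sum(outer(k, k) * Lam / (N * K^2 * S))
  d1 <- sum((k / (2 * K)) * (1 - Lam / (N * lam))) +
    sum((k / (2 * K)) * ops$p * (1 - 2 * Lam / (N * S)))
  d2 <- sum((k / (2 * K)) * (ops$p + ops$p2) * (1 - 2 * Lam / (N * S)))
  e <- network$adj
  edge_sum <- sum((outer(k, k, "-") * outer(lam, lam, "-") * e / S)[upper.tri(e)])
  list(zeta = zeta, delta_lambda1 = d1, delta_lambda2 = d2,
       edge_sum = edge_sum)
}

#' Approximate critical benefit-to-cost ratio (mean-field expansion)
#'
#' Evaluates the expansion
#' \deqn{C^* \approx \frac{N\langle k\rangle^2 \zeta/\langle k^2\rangle - 1
#'   + \Delta_{\lambda^{(1)}} + \Delta_{\tilde\eta_n}}
#'   {N\langle k\rangle \zeta/\langle k^2\rangle - 1
#'   + \Delta_{\lambda^{(2)}} + \Delta_{\tilde\eta_d}}}
#' with \eqn{\zeta = \sum_{i,j} k_i k_j \Lambda / (N K^2 (\lambda_i +
#' \lambda_j))}. The rate-heterogeneity corrections
#' \eqn{\Delta_{\lambda^{(1)}}, \Delta_{\lambda^{(2)}}} are always evaluated
#' exactly. The coalescence-heterogeneity corrections combine
#' \eqn{\Delta_{\tilde\eta^{(2)}}, \Delta_{\tilde\eta^{(3)}}} with
#' \eqn{\Delta_{\tilde\eta^{(\infty)}} \approx (\bar\eta/K^2)\sum_{i<j}
#' (k_i-k_j)(\lambda_i-\lambda_j) e_{ij}/(\lambda_i+\lambda_j)}:
#' \deqn{\Delta_{\tilde\eta_n} = -\Delta_{\tilde\eta^{(2)}} +
#'   \frac{K^2}{\sum_i k_i^2}\Delta_{\tilde\eta^{(\infty)}}, \qquad
#'   \Delta_{\tilde\eta_d} = -\Delta_{\tilde\eta^{(2)}}
#'   -\Delta_{\tilde\eta^{(3)}} +
#'   \frac{KN}{\sum_i k_i^2}\Delta_{\tilde\eta^{(\infty)}}.}
#' With `eta_bar_mode = "from_solve"` the \eqn{\tilde\eta} terms are computed
#' exactly from a coalescence solve (\eqn{\tilde\eta^{(n+1)} = \sum_{i,j,l}
#' (k_i/K) p^{(n)}_{ij} \frac{2\lambda_j}{\lambda_i+\lambda_j} p_{jl}
#' \eta_{il}}, \eqn{\Delta_{\tilde\eta^{(n)}} = \tilde\eta^{(n)} -
#' \eta^{(n)}}) and \eqn{\bar\eta} is the mean pairwise coalescence time.
#' With `eta_bar_mode = "supplied"` no linear system is solved: the caller
#' provides \eqn{\bar\eta} and the large-network closures
#' \eqn{\Delta_{\tilde\eta^{(2)}} \approx N\Delta_{\tilde\eta^{(\infty)}} /
#' \langle k\rangle}, \eqn{\Delta_{\tilde\eta^{(3)}} \approx
#' N\Delta_{\tilde\eta^{(\infty)}} / \langle k\rangle^2} are used, so the
#' cost is dominated by the two matrix products for \eqn{p^{(2)}, p^{(3)}}.
#'
#' At identical update rates all four correction terms vanish and the
#' expression reduces to the classical homogeneous-rate result.
#'
#' @inheritParams solve_coalescence
#' @param eta_bar_mode `"from_solve"` (default) or `"supplied"`.
#' @param eta_bar mean pairwise coalescence time, required (positive) when
#'   `eta_bar_mode = "supplied"`.
#' @return a `cstar_result` with `components` carrying `zeta`, the four
#'   correction terms (`delta_lambda1`, `delta_lambda2`, `delta_eta_n`,
#'   `delta_eta_d`), `delta_eta2`, `delta_eta3`, `delta_eta_inf` and `eta_bar`.
#' @export
cstar_approx <- function(network, rates,
                         eta_bar_mode = c("from_solve", "supplied"),
                         eta_bar = NULL) {
  stopifnot(inherits(network, "coop_network"))
  eta_bar_mode <- match.arg(eta_bar_mode)
  lam <- as_rates(rates, network)
  N <- network$N
  k <- network$deg
  K <- network$K
  kbar <- network$mean_degree
  k2bar <- network$second_moment
  ops <- step_matrices(network)
  bl <- approx_blocks(network, lam, ops)

  if (eta_bar_mode == "from_solve") {
    ct <- solve_coalescence(network, lam)
    eta <- ct$eta
    eta_bar <- ct$eta_bar
    s <- walk_sums(network, eta, ops) / K
    S <- outer(lam, lam, "+")
    M1 <- (k / K) * ops$p * (2 * lam[col(ops$p)] / S)
    M2 <- (k / K) * ops$p2 * (2 * lam[col(ops$p)] / S)
    eta_t2 <- sum((M1 %*% ops$p) * eta)
    eta_t3 <- sum((M2 %*% ops$p) * eta)
    d_inf <- eta_bar / K^2 * bl$edge_sum
    d2 <- eta_t2 - s[["s2"]]
    d3 <- eta_t3 - s[["s3"]]
  } else {
    if (is.null(eta_bar) || !is.finite(eta_bar) || eta_bar <= 0) {
      stop("eta_bar_mode = 'supplied' needs a positive eta_bar", call. = FALSE)
    }
    d_inf <- eta_bar / K^2 * bl$edge_sum
    d2 <- N * d_inf / kbar
    d3 <- N * d_inf / kbar^2
  }
  sumk2 <- sum(k^2)
  d_n <- -d2 + K^2 / sumk2 * d_inf
  d_d <- -d2 - d3 + K * N / sumk2 * d_inf
  num <- N * kbar^2 * bl$zeta / k2bar - 1 + bl$delta_lambda1 + d_n
  den <- N * kbar * bl$zeta / k2bar - 1 + bl$delta_lambda2 + d_d
  new_cstar_result(num / den, num, den, "approx", components = list(
    zeta = bl$zeta,
    delta_lambda1 = bl$delta_lambda1, delta_lambda2 = bl$delta_lambda2,
    delta_eta_n = d_n, delta_eta_d = d_d,
    delta_eta2 = d2, delta_eta3 = d3, delta_eta_inf = d_inf,
    eta_bar = eta_bar, eta_bar_mode = eta_bar_mode
  ))
}

#' Asymptotic critical ratio for large heterogeneous networks
#'
#' Evaluates
#' \deqn{C^* \approx \langle k\rangle + \frac{\langle k\rangle^2 \langle
#'   k^2\rangle \Delta_{\tilde\eta^{(\infty)}}}{\langle k\rangle^3\zeta +
#'   (\langle k\rangle^3 - \langle k\rangle\langle k^2\rangle - \langle
#'   k^2\rangle)\Delta_{\tilde\eta^{(\infty)}}}}
#' and classifies the threshold against the mean degree by the sign of
#' \eqn{\Delta_{\tilde\eta^{(\infty)}} \propto \sum_{i<j}(k_i - k_j)
#' (\lambda_i - \lambda_j) e_{ij}/(\lambda_i + \lambda_j)}: when high-degree
#' nodes update more slowly than their neighbours (every edge term
#' non-positive) the threshold drops below \eqn{\langle k\rangle}; when they
#' update faster it rises above; with identical rates it stays at
#' \eqn{\langle k\rangle}. The classification is independent of the magnitude
#' of `eta_bar`, which only scales the size of the shift.
#'
#' @inheritParams solve_coalescence
#' @param eta_bar positive mean coalescence time; `NULL` (default) computes
#'   it from a coalescence solve.
#' @return a `cstar_result`; `components$classification` is one of
#'   `"below_mean_degree"`, `"near_mean_degree"`, `"above_mean_degree"`, and
#'   `components$mean_degree` the reference \eqn{\langle k\rangle}.
#' @export
cstar_asymptotic <- function(network, rates, eta_bar = NULL) {
  stopifnot(inherits(network, "coop_network"))
  lam <- as_rates(rates, network)
  if (is.null(eta_bar)) {
    eta_bar <- solve_coalescence(network, lam)$eta_bar
  }
  if (!is.finite(eta_bar) || eta_bar <= 0) {
    stop("eta_bar must be positive", call. = FALSE)
  }
  kbar <- network$mean_degree
  k2bar <- network$second_moment
  ops <- step_matrices(network)
  bl <- approx_blocks(network, lam, ops)
  d_inf <- eta_bar / network$K^2 * bl$edge_sum
  num <- kbar^2 * k2bar * d_inf
  den <- kbar^3 * bl$zeta + (kbar^3 - kbar * k2bar - k2bar) * d_inf
  value <- kbar + num / den
  cls <- if (abs(bl$edge_sum) <= 1e-12 * network$K) {
    "near_mean_degree"
  } else if (bl$edge_sum < 0) {
    "below_mean_degree"
  } else {
    "above_mean_degree"
  }
  new_cstar_result(value, value, 1, "asymptotic", components = list(
    zeta = bl$zeta, delta_eta_inf = d_inf, eta_bar = eta_bar,
    mean_degree = kbar, classification = cls
  ))
}

#' First-order fixation probability of cooperation under weak selection
#'
#' \deqn{\rho_C = \frac{1}{N} + \frac{\delta}{\Lambda \sum_i k_i/\lambda_i}
#'   \left[-c \sum_{i,j} k_i p^{(2)}_{ij}\eta_{ij} + b\left(\sum_{i,j} k_i
#'   p^{(3)}_{ij}\eta_{ij} - \sum_{i,j} k_i p_{ij}\eta_{ij}\right)\right]
#'   + O(\delta^2).}
#' At \eqn{b/c = C^*} the first-order correction vanishes and
#' \eqn{\rho_C = 1/N}.
#'
#' @inheritParams solve_coalescence
#' @param b,c benefit and cost of the donation game (both positive).
#' @param delta selection intensity \eqn{\delta \ge 0}.
#' @return list with `rho` (the first-order fixation probability), `slope`
#'   (\eqn{d\rho_C/d\delta} at 0) and `neutral = 1/N`.
#' @export
rho_c_weak_selection <- function(network, rates, b, c, delta) {
  stopifnot(inherits(network, "coop_network"), b > 0, c > 0, delta >= 0)
  lam <- as_rates(rates, network)
  ct <- solve_coalescence(network, lam)
  s <- walk_sums(network, ct$eta)
  slope <- (-c * s[["s2"]] + b * (s[["s3"]] - s[["s1"]])) /
    (sum(lam) * sum(network$deg / lam))
  list(rho = 1 / network$N + delta * slope, slope = slope,
       neutral = 1 / network$N)
}

#' Favourability condition for a general two-player game
#'
#' For a game with payoffs R (mutual cooperation), S (cooperating against a
#' defector), T (defecting against a cooperator) and P (mutual defection),
#' cooperation is favoured over defection on a network with critical
#' donation-game ratio \eqn{C^*} when
#' \deqn{R > R^* = P + (T - S)\frac{C^* - 1}{C^* + 1}.}
#' The donation game (R = b - c, S = -c, T = b, P = 0) reduces this to
#' \eqn{b/c > C^*}.
#'
#' @param R,S,T,P payoff entries of the general game.
#' @param cstar finite critical ratio (scalar or `cstar_result`); must not
#'   equal -1.
#' @return list with `favoured` (logical) and `R_star` (the threshold).
#' @export
general_game_condition <- function(R, S, T, P, cstar) {
  if (inherits(cstar, "cstar_result")) cstar <- cstar$value
  if (!is.finite(cstar)) stop("C* must be finite", call. = FALSE)
  if (abs(cstar + 1) < 1e-12) {
    stop("threshold undefined at C* = -1", call. = FALSE)
  }
  R_star <- P + (T - S) * (cstar - 1) / (cstar + 1)
  list(favoured = R > R_star, R_star = R_star)
}
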