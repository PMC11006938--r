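# Update-rate optimisation: minimise the critical benefit-to-cost ratio over
# per-node update rates by RMSProp gradient descent in theta, where
# lambda_i = exp(theta_i) keeps every rate positive. The gradient is obtained
# by implicit differentiation of the coalescence linear system: all N
# derivative systems share the operator of the eta solve, so one
# eigendecomposition per iteration serves the solve and every coordinate.

# dC*/deta as a full symmetric matrix Gd with dC* = (1/2) sum_ij Gd_ij deta_ij
cstar_eta_sensitivity <- function(network, ops, eta) {
  k <- network$deg
  s1 <- sum(k * ops$p * eta)
  s2 <- sum(k * ops$p2 * eta)
  s3 <- sum(k * ops$p3 * eta)
  den <- s3 - s1
  cstar <- s2 / den
  aa <- k * ops$p2
  bb <- k * (ops$p3 - ops$p)
  list(Gd = ((aa + t(aa)) - cstar * (bb + t(bb))) / den, cstar = cstar)
}

#' Gradient of the critical ratio with respect to log update rates
#'
#' Computes \eqn{\partial C^*/\partial\theta_i} (\eqn{\lambda_i =
#' e^{\theta_i}}) by implicit differentiation: differentiating the
#' coalescence recurrence in \eqn{\lambda_i} yields, for every i, a linear
#' system with the same operator as the coalescence solve and a new constant
#' term, so a single sparse LU factorisation of the pair system is reused
#' across all N right-hand sides; the chain rule through \eqn{\partial
#' C^*/\partial\eta} (from the exact critical-ratio formula) and
#' \eqn{\partial\lambda_i/\partial\theta_i = \lambda_i} completes the
#' gradient. Because \eqn{C^*} is invariant to a common rescaling of all
#' rates, the gradient always sums to zero (it is orthogonal to the all-ones
#' direction).
#'
#' @inheritParams solve_coalescence
#' @return list with `gradient` (length N, with respect to theta), `cstar`,
#'   and `eta` (the coalescence matrix at the evaluation point).
#' @export
cstar_gradient <- function(network, rates) {
  stopifnot(inherits(network, "coop_network"))
  lam <- as_rates(rates, network)
  N <- network$N
  ps <- pair_system(network, lam)
  f <- pair_factor(ps)
  x <- as.numeric(Matrix::solve(f, ps$rhs))
  eta <- eta_from_pairs(ps, x, N)
  res <- eta_residual(network, lam, eta)
  if (!is.finite(res) || res > 1e-8 * max(1, max(abs(eta)))) {
    stop(sprintf("coalescence solve in gradient: residual %.3e", res),
         call. = FALSE)
  }
  ops <- step_matrices(network)
  sens <- cstar_eta_sensitivity(network, ops, eta)
  # derivative right-hand sides, one column per lambda_m: differentiating the
  # pair equations (multiplied through by s_ij) gives
  #   1/N + [i = m]((P eta)_mj - eta_mj) + [j = m]((P eta)_mi - eta_mi),
  # rescaled by the same row weights w as the symmetrised operator
  U <- ops$p %*% eta - eta
  pi_ <- ps$pairs[, 1]
  pj_ <- ps$pairs[, 2]
  Rmat <- matrix(ps$w / N, ps$M, N)
  Rmat[cbind(seq_len(ps$M), pi_)] <- Rmat[cbind(seq_len(ps$M), pi_)] +
    U[cbind(pi_, pj_)] * ps$w
  Rmat[cbind(seq_len(ps$M), pj_)] <- Rmat[cbind(seq_len(ps$M), pj_)] +
    U[cbind(pj_, pi_)] * ps$w
  deta <- as.matrix(Matrix::solve(f, Rmat))
  w <- sens$Gd[ps$pairs]
  g <- as.numeric(crossprod(deta, w)) * lam
  if (any(!is.finite(g))) stop("non-finite gradient", call. = FALSE)
  list(gradient = g, cstar = sens$cstar, eta = eta)
}

#' Optimise per-node update rates to minimise the critical ratio
#'
#' RMSProp gradient descent on \eqn{\theta} with \eqn{\lambda_i =
#' e^{\theta_i}}: per iteration the coalescence system is solved, the
#' critical ratio and its implicit gradient are evaluated, the squared
#' gradient accumulator is decayed (\eqn{r \leftarrow \rho r + (1-\rho) g
#' \odot g}) and \eqn{\theta \leftarrow \theta - \epsilon g / \sqrt{\delta_
#' {opt} + r}}. Iteration stops when the mean absolute step falls below `tol`
#' or after `max_iter` iterations.
#'
#' On exactly vertex-transitive graphs the uniform point is a symmetric
#' stationary point (every gradient component equal), so the identical-rate
#' profile does not move; `perturb` optionally adds a small seeded
#' perturbation to the initial theta to break such symmetry.
#'
#' @inheritParams solve_coalescence
#' @param epsilon learning rate (default 1).
#' @param decay squared-gradient decay rate in (0, 1) (default 0.9).
#' @param delta_opt stabiliser added under the square root (default 1e-6).
#' @param tol convergence tolerance on the mean absolute theta step
#'   (default 1e-6).
#' @param max_iter iteration cap (default 1000).
#' @param theta0 initial theta (default all zeros, i.e. identical rates).
#' @param perturb scale of an optional seeded normal perturbation of the
#'   initial theta (default 0 = off).
#' @param seed seed for the perturbation.
#' @return object of class `optimization_trace`: data frame `trace` (columns
#'   `iter`, `cstar`, `mean_abs_step`, `grad_norm`), matrices `theta_path`
#'   and `lambda_path` (iterations x N), final `lambda`, `cstar`, `status`
#'   (`"converged"` or `"max_iter"`).
#' @examples
#' \donttest{
#' ba <- generate_network("scale_free_ba", N = 30, seed = 1)
#' opt <- optimise_rates(ba, max_iter = 50)
#' opt$cstar < cstar_exact(ba, 1)$value
#' }
#' @export
optimise_rates <- function(network, epsilon = 1, decay = 0.9,
                           delta_opt = 1e-6, tol = 1e-6, max_iter = 1000,
                           theta0 = NULL, perturb = 0, seed = NULL) {
  stopifnot(inherits(network, "coop_network"),
            epsilon > 0, decay > 0, decay < 1, delta_opt > 0, max_iter >= 1)
  N <- network$N
  theta <- theta0 %||% rep(0, N)
  stopifnot(length(theta) == N)
  if (perturb > 0) {
    theta <- theta + with_local_seed(seed, rnorm(N, 0, perturb))
  }
  r <- rep(0, N)
  trace <- vector("list", max_iter)
  theta_path <- matrix(NA_real_, max_iter, N)
  status <- "max_iter"
  for (it in seq_len(max_iter)) {
    gr <- cstar_gradient(network, exp(theta))
    r <- decay * r + (1 - decay) * gr$gradient^2
    step <- -epsilon / sqrt(delta_opt + r) * gr$gradient
    theta <- theta + step
    theta_path[it, ] <- theta
    trace[[it]] <- data.frame(
      iter = it, cstar = gr$cstar,
      mean_abs_step = mean(abs(step)),
      grad_norm = sqrt(sum(gr$gradient^2))
    )
    if (mean(abs(step)) <= tol) {
      status <- "converged"
      break
    }
  }
  used <- seq_len(it)
  trace <- do.call(rbind, trace[used])
  lambda <- exp(theta)
  final <- cstar_exact(network, lambda)
  structure(
    list(
      trace = trace, theta_path = theta_path[used, , drop = FALSE],
      lambda_path = exp(theta_path[used, , drop = FALSE]),
      theta = theta, lambda = lambda,
      cstar = final$value, regime = final$regime, status = status
    ),
    class = "optimization_trace"
  )
}

#' @export
print.optimization_trace <- function(x, ...) {
  cat(sprintf("<optimization_trace> %d iterations (%s): C* %.6g -> %.6g\n",
              nrow(x$trace), x$status, x$trace$cstar[1], x$cstar))
  invisible(x)
}
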