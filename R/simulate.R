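# R surface of the event-driven Monte-Carlo engine (see src/simulate.cpp).
# Poisson update clocks are realised as a discrete event chain: the next
# updater is node i with probability lambda_i / Lambda (competing
# exponentials), so all reported quantities are event-indexed and only rate
# ratios matter. Selection probabilities are normalised in R before being
# passed down, which keeps trajectories bit-identical under a rescaling of
# all rates with a shared seed.

sim_inputs <- function(network, rates, b, c, delta) {
  stopifnot(inherits(network, "coop_network"))
  lam <- as_rates(rates, network)
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  if (delta * c >= 1) {
    stop("selection too strong: need delta * c < 1 so all fitnesses stay positive",
         call. = FALSE)
  }
  list(edges = network$edges, N = network$N, probs = lam / sum(lam))
}

#' Simulate fixation of cooperation
#'
#' Runs independent realisations of the evolutionary process, each started
#' from a single cooperator placed uniformly at random among N - 1 defectors
#' and ended at an absorbing state (all-C or all-D). Per event, node i is
#' selected to update with probability \eqn{\lambda_i/\Lambda} and copies a
#' neighbour j with probability proportional to its fitness \eqn{F_j = 1 +
#' \delta f_j} among i's neighbours.
#'
#' @inheritParams rho_c_weak_selection
#' @param n_runs number of independent realisations.
#' @param seed master seed; run r uses its own stream derived from
#'   (seed, r), so results do not depend on execution order.
#' @param collect_stats also pool the local cooperator-frequency statistics
#'   (see [measure_Q()]).
#' @param event_budget per-run safety cap on events (default 1e8); exceeding
#'   it is an error, never a silent truncation.
#' @return object of class `fixation_estimate`: `n_runs`, `n_fix_C`,
#'   `rho_hat`, `se` (binomial standard error), `mean_events`, and when
#'   `collect_stats` a `local_stats` element as returned by [measure_Q()].
#' @examples
#' net <- generate_network("complete", N = 2)
#' simulate_fixation(net, 1, b = 3, c = 1, delta = 0.05,
#'                   n_runs = 200, seed = 1)$rho_hat   # exactly 1/2 process
#' @export
simulate_fixation <- function(network, rates, b, c, delta, n_runs, seed,
                              collect_stats = FALSE, event_budget = 1e8) {
  stopifnot(n_runs >= 1)
  inp <- sim_inputs(network, rates, b, c, delta)
  out <- .sim_fixation_cpp(inp$edges, inp$N, inp$probs, b, c, delta,
                           as.integer(n_runs), as.double(seed),
                           collect_stats, event_budget)
  rho_hat <- out$n_fix_C / n_runs
  res <- structure(
    list(
      n_runs = n_runs, n_fix_C = out$n_fix_C, rho_hat = rho_hat,
      se = sqrt(rho_hat * (1 - rho_hat) / n_runs),
      mean_events = out$mean_events
    ),
    class = "fixation_estimate"
  )
  if (collect_stats) {
    res$local_stats <- local_stats(network, out)
  }
  res
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf("<fixation_estimate> rho_hat = %.5f (se %.5f) from %d runs, %.1f events/run\n",
              x$rho_hat, x$se, x$n_runs, x$mean_events))
  invisible(x)
}

local_stats <- function(network, out) {
  km1 <- network$mean_degree - 1
  cls <- out$extras$degree_classes
  colnames(cls) <- c("n_C_ends", "q_CC", "n_D_ends", "q_CD")
  structure(
    list(
      q_CC = out$q_CC, q_CD = out$q_CD,
      Q = (out$q_CC - out$q_CD) * km1,
      n_interface_events = out$n_interface_events,
      q_CC_global = out$q_CC_global, q_CD_global = out$q_CD_global,
      Q_global = (out$q_CC_global - out$q_CD_global) * km1,
      n_coex_events = out$n_coex_events,
      degree_classes = cls[rowSums(cls[, c(1, 3), drop = FALSE]) > 0, ,
                           drop = FALSE]
    ),
    class = "local_freq_stats"
  )
}

#' @export
print.local_freq_stats <- function(x, ...) {
  cat(sprintf("<local_freq_stats> q_C|C = %.4f, q_C|D = %.4f, Q = %.4f (%g interface events)\n",
              x$q_CC, x$q_CD, x$Q, x$n_interface_events))
  cat(sprintf("  global: q_C|C = %.4f, q_C|D = %.4f, Q = %.4f (%g coexistence events)\n",
              x$q_CC_global, x$q_CD_global, x$Q_global, x$n_coex_events))
  invisible(x)
}

#' Pooled local cooperator-frequency statistics
#'
#' Measures the surplus of cooperative neighbours that a cooperator has over
#' a defector along the evolutionary process, as
#' \deqn{Q = (q_{C|C} - q_{C|D})(\langle k\rangle - 1).}
#' The primary estimator is the competition statistic of the pair argument:
#' at every update event whose updating node has both a cooperating and a
#' defecting neighbour, `q_CC` is the average cooperator fraction among the
#' remaining neighbours of those cooperating neighbours (the updating node
#' itself is excluded, since its contribution to both competitors is equal)
#' and `q_CD` the analogue for defecting neighbours; events are pooled with
#' equal weight across runs. Pair approximation predicts Q = 1 on large
#' regular graphs with identical update rates under neutral drift — at finite
#' N the measured value matches the exact threshold via
#' \eqn{Q = \langle k\rangle / C^*}, i.e. \eqn{(N-2k)/(N-2)} on a k-regular
#' graph — and slow (fast) hub updating pushes Q up (down). A secondary
#' whole-graph statistic is also returned (`q_CC_global`, `q_CD_global`,
#' `Q_global`): the edge-weighted conditional cooperator frequencies over all
#' nodes, recorded at every event where both strategies coexist anywhere.
#'
#' @inheritParams simulate_fixation
#' @param b,c game payoffs; irrelevant when `delta = 0` (defaults 6 and 1).
#' @return a `local_freq_stats` object (fields `q_CC`, `q_CD`, `Q`,
#'   `n_coex_events`).
#' @export
measure_Q <- function(network, rates, delta, n_runs, seed, b = 6, c = 1,
                      event_budget = 1e8) {
  simulate_fixation(network, rates, b, c, delta, n_runs, seed,
                    collect_stats = TRUE, event_budget = event_budget)$local_stats
}

#' Long-term payoffs under mutation
#'
#' Runs a single long realisation of the process in which, whenever the
#' population is absorbed in full cooperation or full defection, a uniformly
#' chosen node flips its strategy with probability `u` (an event elapses
#' either way). Per-node payoffs \eqn{f_i = -c x_i + b \sum_j p_{ij} x_j} are
#' recomputed from the current state and averaged over all events.
#'
#' @inheritParams simulate_fixation
#' @param u mutation probability at absorbing states (0 < u <= 1 for ergodic
#'   runs; u = 0 from an absorbing start degenerates to a frozen population
#'   and raises a warning).
#' @param n_events number of events to simulate.
#' @param start `"all_D"` (default), `"all_C"`, or `"single_C"` for one
#'   uniformly placed cooperator.
#' @return object of class `long_term_payoffs`: `mean_payoff` (per node),
#'   `overall` (population mean), `frac_all_C`, `frac_all_D`, `u`,
#'   `n_events`.
#' @export
simulate_longterm <- function(network, rates, b, c, delta, u, n_events, seed,
                              start = c("all_D", "all_C", "single_C")) {
  start <- match.arg(start)
  stopifnot(u >= 0, u <= 1, n_events >= 1)
  inp <- sim_inputs(network, rates, b, c, delta)
  if (u == 0 && start != "single_C") {
    warning("u = 0 from an absorbing start: the population stays frozen")
  }
  start_code <- switch(start, all_D = 0L, all_C = 1L, single_C = -1L)
  out <- .sim_longterm_cpp(inp$edges, inp$N, inp$probs, b, c, delta, u,
                           as.double(n_events), as.double(seed), start_code)
  structure(
    list(
      mean_payoff = out$mean_payoff, overall = mean(out$mean_payoff),
      frac_all_C = out$frac_all_C, frac_all_D = out$frac_all_D,
      u = u, n_events = n_events
    ),
    class = "long_term_payoffs"
  )
}

#' @export
print.long_term_payoffs <- function(x, ...) {
  cat(sprintf("<long_term_payoffs> overall = %.5f over %g events (all-C %.3f, all-D %.3f)\n",
              x$overall, x$n_events, x$frac_all_C, x$frac_all_D))
  invisible(x)
}
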