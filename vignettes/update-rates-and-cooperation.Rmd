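---
title: "Personalised update rates and the fixation of cooperation on networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalised update rates and the fixation of cooperation on networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`coopfix` studies the donation game on an undirected, simple, connected
network of `N` players. A cooperator pays a cost `c` to deliver a benefit `b`
to each neighbour; defectors pay and deliver nothing, so the pairwise payoff
matrix is `R = b - c`, `S = -c`, `T = b`, `P = 0`. The state is a binary
vector `x`, and player i's average payoff is

    f_i(x) = -c x_i + b * sum_j p_ij x_j,     p_ij = e_ij / k_i,

the average over i's neighbourhood. What distinguishes the model from the
canonical death-birth process is that every node carries its own update rate
`lambda_i > 0`: node i revises its strategy at the events of a Poisson
process with intensity `lambda_i`. When i revises, it copies neighbour j with
probability proportional to j's fitness `F_j = 1 + delta * f_j` among i's
neighbours; `delta >= 0` is the selection intensity, and all analysis is to
first order in `delta` (weak selection). Fitness positivity requires
`delta * c < 1`.

Because only the order of update events matters for every quantity the
package reports, the competing Poisson clocks are realised as a discrete
event chain: the next updater is node i with probability
`lambda_i / Lambda`, `Lambda = sum(lambda)`. All results are therefore
invariant to a common rescaling of the rates, and the package's tests assert
this invariance for every computational route.

The central quantity is the critical benefit-to-cost ratio `C*`: the
fixation probability `rho_C` of a single cooperator placed uniformly at
random exceeds the neutral value `1/N` (to first order in `delta`) exactly
when `b/c > C*`. The package computes `C*` three ways.

## The exact critical ratio

Under neutral drift the relevant correlations are meeting times of
rate-weighted coalescing random walks: `eta_ij` solves

    eta_ij = Lambda / (N (lambda_i + lambda_j))
             + sum_k [lambda_i/(lambda_i+lambda_j)] p_ik eta_kj
             + sum_k [lambda_j/(lambda_i+lambda_j)] p_jk eta_ki,   eta_ii = 0,

and the exact threshold is the ratio of eta-weighted walk sums

    C* = sum_ij k_i p2_ij eta_ij /
         (sum_ij k_i p3_ij eta_ij - sum_ij k_i p_ij eta_ij),

with `p2`, `p3` the two- and three-step walk matrices (`cstar_exact()`). The
double sums run over ordered pairs including `i = j`; the diagonal terms
vanish since `eta_ii = 0`. A negative denominator means no finite benefit
favours cooperation (`regime = "never_favoured"`; the complete graph K3,
where `C* = -2`, is the canonical spite example), and a vanishing
denominator is reported as `"divergent"`. On a vertex-transitive k-regular
graph with identical rates the formula collapses to the closed form
`k(N-2)/(N-2k)`, which the tests use as an oracle (cycle of 6: `C* = 4`).

The first-order fixation probability itself is available as
`rho_c_weak_selection()`:

    rho_C = 1/N + delta / (Lambda * sum_i k_i/lambda_i) *
            [ -c * S2 + b * (S3 - S1) ] + O(delta^2),

with `S_n = sum_ij k_i pn_ij eta_ij`. Reproductive values
`pi_i = (k_i/lambda_i) / sum_l (k_l/lambda_l)` (`reproductive_values()`)
weight each node's contribution under neutral drift; the package validates
the form by the martingale property of `sum_i pi_i x_i` rather than by a
closed-form derivation, and the whole expression is validated against an
independent brute-force route (below) to 1e-8 relative.

## Solving the coalescence system

`solve_coalescence()` offers three solvers, cross-checked against each other
in the tests.

* **`"pairs"` (default).** The recurrence, multiplied through by
  `s_ij = lambda_i + lambda_j`, is a sparse linear system in the
  `N(N-1)/2` unordered pairs. Scaling the `{i,j}` row by
  `w_ij = 1/(s_i s_j)` with `s_i = lambda_i/k_i` makes the operator
  symmetric: the coupling of pair `{i,j}` to `{k,j}` along an edge `(i,k)`
  becomes `1/s_j` from both sides. The scaled matrix is irreducibly
  diagonally dominant with positive diagonal, hence symmetric positive
  definite, and a sparse supernodal Cholesky factorisation solves it (a
  fraction of a second at N = 100 on one core). The decisive property is
  *scaling robustness*: all structural coefficients of the equilibrated
  system are bounded, so solutions remain accurate to machine precision even
  when rates span tens of orders of magnitude — which they genuinely do
  along an optimisation trajectory (see below).
* **`"eigen"`.** `A = D_lambda (I - P)` is similar to the symmetric matrix
  `S^(1/2) L S^(1/2)` (`L` the graph Laplacian, `S = diag(lambda_i/k_i)`),
  so the equivalent Lyapunov equation
  `A eta + eta A^T = (Lambda/N)(J - I) + diag(phi)` — with unknown diagonal
  sources `phi` enforcing `eta_ii = 0` and one free mode along the
  zero-eigenvalue direction — diagonalises in `O(N^3)`. This is the fastest
  route for moderate rate spreads but, like any symmetric eigensolver,
  computes small eigenvalues with absolute rather than relative accuracy, so
  it degrades once rate ratios exceed roughly 1e12. A step of iterative
  refinement on the defect extends its range; the default solver does not
  have this limitation.
* **`"fixed_point"`.** Jacobi iteration of the recurrence itself, kept as a
  structurally independent cross-check and for memory-constrained large
  problems.

Residuals are always verified against the recurrence in its natural form and
accepted at `1e-10` (direct) or `1e-8` (fixed point), scaled by the
magnitude of `eta`; a failed check is an error, never a silent degradation.

## The mean-field expansion and the sign rule

Solving the pair system costs `O(N^3)` with the sparse factorisation but the
expansion behind `cstar_approx()` avoids the solve altogether when an
estimate of the mean coalescence time `eta_bar` is available:

    C* ~ (N <k>^2 zeta / <k^2> - 1 + D_l1 + D_en) /
         (N <k>  zeta / <k^2> - 1 + D_l2 + D_ed)

with `zeta = sum_ij k_i k_j Lambda / (N K^2 (lambda_i + lambda_j))` (equal
to 1/2 at identical rates) and four correction terms: two rate-heterogeneity
terms evaluated exactly from their definitions, and two coalescence terms
assembled from `D_inf ~ (eta_bar/K^2) sum_{i<j} (k_i - k_j)(lambda_i -
lambda_j) e_ij / (lambda_i + lambda_j)`. With `eta_bar_mode = "from_solve"`
the eta-tilde building blocks are computed exactly from a coalescence solve;
with `"supplied"` the large-network closures `D_eta2 ~ N D_inf / <k>`,
`D_eta3 ~ N D_inf / <k>^2` are used and the cost is dominated by two matrix
products. All four corrections vanish identically at identical rates, which
the acceptance checks assert at 1e-12.

For large heterogeneous networks `cstar_asymptotic()` reduces the expansion
further to a shift of the mean degree whose *sign* is decided by
`sum_{i<j} (k_i - k_j)(lambda_i - lambda_j) e_ij / (lambda_i + lambda_j)`:
if higher-degree nodes update more slowly than their neighbours the
threshold drops below `<k>`, if they update faster it rises above, and with
identical rates it stays at `<k>`. Only this sign classification is treated
as a hard contract; the magnitude of the shift depends on `eta_bar`, whose
fast estimation is outside the package's scope (the caller supplies it, or a
solve provides the pairwise mean).

## The exact finite-state oracle

For `N <= 12` the whole process is an absorbing Markov chain on the `2^N`
strategy configurations (`exact_fixation()`). The package builds the full
kernel from the imitation rule, eliminates the two absorbing states and
solves the absorption system; `weak_selection_derivative()` differentiates
that system analytically at `delta = 0` (each fitness is affine in `delta`)
with a centred finite-difference cross-check, and `empirical_cstar()`
bisects the benefit for the derivative's sign change. This brute-force route
shares no code with the coalescence formula, which is what makes the
agreement test between the two meaningful: on random connected graphs with
random rates the bisected threshold matches `cstar_exact()` to 1e-6
relative, or both report that no finite positive threshold exists.

## The Monte-Carlo engine

`simulate_fixation()` runs the event chain in compiled code. Each run has
its own xoshiro256+ stream derived from `(seed, run index)`, so estimates
are independent of execution order and bit-reproducible; selection
probabilities are normalised once (`lambda/sum(lambda)`), which makes
trajectories bit-identical under rate rescaling with a shared seed. Runs
start from one uniformly placed cooperator and stop at an absorbing state —
imitation dynamics on a connected graph absorbs with probability one, and
the configurable per-run event budget (default 1e8) is a safety net whose
exhaustion is an error, never a truncation. Payoffs are recomputed from the
current state at each event; nothing is accumulated across rounds.
`simulate_longterm()` adds the mutation protocol: whenever the population is
absorbed, a uniformly chosen node flips with probability `u` (an event
elapses either way), and per-node payoffs are averaged over all events —
event-averaging is this package's documented choice where the averaging
window is otherwise underdetermined.

### The local pair statistic Q

The mechanism behind the update-rate effects is local: when a node revises,
a cooperating and a defecting neighbour compete for it, and the cooperator
wins more often when its *other* neighbours cooperate more than the
defector's do. `measure_Q()` therefore records, at every update event whose
updating node has both kinds of neighbours, the average cooperator fraction
among the remaining `k - 1` neighbours of the competing cooperators
(`q_CC`) and defectors (`q_CD`), excluding the updating node itself (its
contribution to both competitors is equal), pooling events with equal
weight across runs:

    Q = (q_CC - q_CD) * (<k> - 1).

Pair approximation gives `Q = 1` on regular graphs with identical rates
under neutral drift — in the large-population limit. At finite `N` the
statistic is *exactly* tied to the threshold through the mechanism relation
`C* = <k>/Q`: on a k-regular graph `Q = k/C*(N) = (N-2k)/(N-2)`, which is
0.792 at N = 50, 0.898 at N = 100 and 0.966 at N = 300. The test suite and
the acceptance script measure exactly this finite-size curve at those three
sizes (about 0.78, 0.90 and 0.97 respectively, converging to 1 from below);
asserting `Q = 1.00 +/- 0.05` at N = 100 would contradict the exact theory,
and the test suite says so explicitly. Two plausible alternative estimators were examined and rejected
because they do not estimate the mechanism quantity at all: pooling raw
edge-end counts over the whole trajectory lets high-cooperator-frequency
events dominate the numerator of `q_CC` (measured 2.35 on the same
conditions), while the per-event whole-graph conditional frequencies lack
the competition conditioning and the updater exclusion (measured 0.685).
The whole-graph per-event statistic is still returned (`Q_global`) as a
diagnostic, alongside a per-degree-class breakdown of the interface
statistic.

Under selection (`delta = 0.01`) the statistic orders exactly as the hub
argument predicts: on a 100-node scale-free network, `Q(lambda = 1/k) >
Q(identical) > Q(lambda = k)` (measured 0.94 > 0.78 > 0.63), the finite-N
form of the statement that slow hubs hold `Q` above its identical-rate
value and fast hubs push it below.

## Optimising the update rates

`optimise_rates()` minimises `C*` over rates by RMSProp gradient descent in
`theta` with `lambda = exp(theta)` (positivity by construction): per
iteration the coalescence system is solved, the gradient is obtained by
implicit differentiation — each `d eta / d lambda_m` solves a system with
the *same* operator and a new right-hand side, so the one sparse Cholesky
factorisation serves all `N` coordinates — and

    r <- rho * r + (1 - rho) * g * g
    theta <- theta - epsilon * g / sqrt(delta_opt + r)

with defaults `epsilon = 1`, `rho = 0.9`, `delta_opt = 1e-6`, stopping when
`mean(|d theta|) <= 1e-6` or after `max_iter = 1000` iterations. The
gradient is verified against central finite differences (1e-5 relative) in
the tests. Two structural facts shape the implementation:

* `C*` is invariant to uniform shifts of `theta`, so the gradient sums to
  zero and the iteration may drift along that flat direction; convergence is
  declared on the mean absolute step, which tolerates the drift. An optional
  centring is deliberately omitted to keep the update exactly as specified.
* The optimum on heterogeneous graphs pushes hub rates towards zero
  asymptotically rather than to an interior point: on a 100-node scale-free
  network, 200 iterations take `C*` from 7.06 (identical rates) to 4.45 —
  already below the `lambda = 1/k` heuristic's 5.67 — while `theta` spreads
  over tens of log-units. This is why the solver's robustness to extreme
  rate ratios is not a luxury; with rates spanning `e^40` the factorisation
  still returns machine-precision residuals. The final rate profile
  correlates negatively with degree (Spearman -0.83 in that run), the
  quantitative form of the design rule that better-connected nodes should
  update more slowly.
* On exactly vertex-transitive graphs the uniform profile is a symmetric
  stationary point: every gradient component is equal, so the identical-rate
  point does not move. The `perturb` option adds a small seeded normal
  perturbation (suggested scale 1e-3) to the initial `theta` to break such
  symmetry when exploring; it is off by default.

## The synthetic-network generator

`generate_network()` provides the topologies the theory is exercised on:
a triangular lattice on a torus (every node has exactly six neighbours;
dimensions default to 7 x 14, N = 98 — the periodic choice makes the graph
vertex-transitive, avoiding boundary effects the theory does not model),
Erdos-Renyi, Watts-Strogatz small-world (rewiring probability default 0.7,
the one value the source material states; it is a free parameter),
Barabasi-Albert with `m = 3` so that the mean degree is close to 6,
random regular, configuration-model, uniform-attachment, double-star, cycle
and complete graphs. Models without guaranteed connectivity are resampled
(up to 1000 attempts) until connected, keeping generation deterministic per
seed. Sampled rate distributions default to uniform(0.5, 1.5), normal(1,
0.25) truncated at 0.05, exponential(mean 1) and Pareto(tail 2.5, min 0.1);
these are conventional choices recorded in the profile metadata, made once
and configurable.

What the generator deliberately does not emulate: degree correlations,
community structure, weighted or directed ties, and temporal rewiring. A
green test suite therefore supports the mathematics on static undirected
graphs, not claims about any particular empirical contact network — users
can load their own edge lists through `read_edge_list()` for that.

## Problem sizes and numerical choices

The test and acceptance workloads use N around 100 (98 for the lattice) with
mean degree 6, 5,000-100,000 Monte-Carlo runs, and 60-200 optimiser
iterations; these sizes make every check reproducible on a laptop core in
minutes while keeping the finite-size behaviour of each statistic visible
rather than hidden. Exact-chain cross-checks cap at `N = 12` (4096 states).
Ties and degenerate inputs are handled by explicit contracts: duplicate
edges collapse, self-loops and disconnected inputs are errors with component
reports, infeasible generator parameters (odd `N * k` for random regular
graphs, non-graphical degree sequences) are parameter errors, `u = 0` from
an absorbing start warns about the frozen run, and `delta * c >= 1` is
rejected everywhere.

## Known limitations

* The mean-field expansion's accuracy on strongly heterogeneous networks
  with strongly heterogeneous rates is diagnostic, not guaranteed; the test
  suite bounds its deviation loosely and reports it rather than gating on
  it.
* `eta_bar` has no fast estimator in the package; magnitude-dependent uses
  of the asymptotic formula require the caller to supply it.
* The optimiser inherits RMSProp's behaviour on flat valleys: with the
  specified stopping rule it typically hits the iteration cap while the
  objective has long plateaued; the trace makes this visible.
* Only imitation (death-birth) updating with multiplicative fitness
  `1 + delta f` is implemented; birth-death and pairwise-comparison rules
  are out of scope, as are multi-strategy games and temporal networks.
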