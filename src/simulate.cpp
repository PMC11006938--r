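// Event-driven Monte-Carlo engine for the donation game with personalised
// update rates. Per event: node i is selected with probability
// lambda_i / Lambda, then copies neighbour j with probability proportional
// to F_j = 1 + delta * f_j among its neighbours, where
// f_j = -c x_j + (b / k_j) * (# cooperating neighbours of j).
//
// RNG: self-contained xoshiro256+ with splitmix64 seeding so that every run
// has its own stream derived from (master seed, run index); results are
// therefore independent of execution order and identical across platforms.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // uniform in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
};

struct Graph {
  int N;
  std::vector<int> nb;     // concatenated neighbour lists
  std::vector<int> start;  // CSR offsets, length N + 1
  std::vector<double> deg;
};

Graph make_graph(const IntegerMatrix& edges, int N) {
  Graph g;
  g.N = N;
  std::vector<std::vector<int>> adj(N);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  g.start.resize(N + 1, 0);
  g.deg.resize(N);
  for (int i = 0; i < N; ++i) {
    g.start[i + 1] = g.start[i] + (int)adj[i].size();
    g.deg[i] = (double)adj[i].size();
  }
  g.nb.reserve(g.start[N]);
  for (int i = 0; i < N; ++i) {
    for (int j : adj[i]) g.nb.push_back(j);
  }
  return g;
}

// state of one realisation
struct Sim {
  const Graph& g;
  std::vector<int> x;       // strategy per node (1 = cooperator)
  std::vector<int> ncoop;   // cooperating neighbours per node
  int n_coop;               // total cooperators
  explicit Sim(const Graph& g_) : g(g_), x(g_.N, 0), ncoop(g_.N, 0), n_coop(0) {}

  void reset_single(int mutant) {
    std::fill(x.begin(), x.end(), 0);
    std::fill(ncoop.begin(), ncoop.end(), 0);
    x[mutant] = 1;
    n_coop = 1;
    for (int t = g.start[mutant]; t < g.start[mutant + 1]; ++t) ncoop[g.nb[t]] = 1;
  }
  void reset_all(int val) {
    std::fill(x.begin(), x.end(), val);
    n_coop = val ? g.N : 0;
    for (int i = 0; i < g.N; ++i) ncoop[i] = val ? (int)g.deg[i] : 0;
  }
  void set_strategy(int i, int v) {
    if (x[i] == v) return;
    x[i] = v;
    int d = v ? 1 : -1;
    n_coop += d;
    for (int t = g.start[i]; t < g.start[i + 1]; ++t) ncoop[g.nb[t]] += d;
  }
  inline double payoff(int i, double b, double c) const {
    return -c * x[i] + b * ncoop[i] / g.deg[i];
  }
  // select the updating node with probability lambda_i / Lambda
  int pick_updater(Xoshiro& rng, const std::vector<double>& cum_lambda) const {
    double u = rng.unif();
    int i = (int)(std::lower_bound(cum_lambda.begin(), cum_lambda.end(), u) -
                  cum_lambda.begin());
    return i >= g.N ? g.N - 1 : i;
  }
  // node i copies one of its neighbours with probability proportional to
  // fitness F_j = 1 + delta f_j
  void imitate(int i, Xoshiro& rng, double b, double c, double delta) {
    int lo = g.start[i], hi = g.start[i + 1];
    int j;
    if (delta == 0.0) {
      j = g.nb[lo + (int)(rng.unif() * (hi - lo))];
    } else {
      double tot = 0.0;
      for (int t = lo; t < hi; ++t) tot += 1.0 + delta * payoff(g.nb[t], b, c);
      double v = rng.unif() * tot;
      double acc = 0.0;
      j = g.nb[hi - 1];
      for (int t = lo; t < hi; ++t) {
        acc += 1.0 + delta * payoff(g.nb[t], b, c);
        if (v < acc) { j = g.nb[t]; break; }
      }
    }
    set_strategy(i, x[j]);
  }
  void step(Xoshiro& rng, const std::vector<double>& cum_lambda,
            double b, double c, double delta) {
    imitate(pick_updater(rng, cum_lambda), rng, b, c, delta);
  }
};

std::vector<double> cum_from_probs(const NumericVector& probs) {
  std::vector<double> cum(probs.size());
  double acc = 0.0;
  for (int i = 0; i < probs.size(); ++i) {
    acc += probs[i];
    cum[i] = acc;
  }
  cum[probs.size() - 1] = 1.0;
  return cum;
}

}  // namespace

// [[Rcpp::export(name = ".sim_fixation_cpp")]]
List sim_fixation_cpp(IntegerMatrix edges, int N, NumericVector probs,
                      double b, double c, double delta, int n_runs,
                      double seed, bool collect_q, double event_budget) {
  Graph g = make_graph(edges, N);
  std::vector<double> cum = cum_from_probs(probs);
  Sim sim(g);
  long long n_fix = 0;
  double total_events = 0.0;
  // Local cooperator-frequency statistics, two flavours, each pooled with
  // equal weight per qualifying event:
  //  * global: edge-weighted conditional frequencies over the whole graph at
  //    every event where both strategies coexist;
  //  * interface: among the neighbours of the updating node, at events where
  //    that neighbourhood contains both a cooperator and a defector, with
  //    the updating node excluded from each neighbour's own count (the
  //    competition-for-the-updating-site statistic of the pair argument).
  double qc_sum = 0.0, qd_sum = 0.0, n_coex = 0.0;
  double ic_sum = 0.0, id_sum = 0.0, n_iface = 0.0;
  int max_deg = 0;
  for (int i = 0; i < N; ++i) max_deg = std::max(max_deg, (int)g.deg[i]);
  // per-degree-class breakdown of the interface statistic (neighbour degree)
  std::vector<double> cls_c(max_deg + 1, 0.0), cls_cn(max_deg + 1, 0.0);
  std::vector<double> cls_d(max_deg + 1, 0.0), cls_dn(max_deg + 1, 0.0);

  for (int run = 0; run < n_runs; ++run) {
    Xoshiro rng((uint64_t)seed * 0x100000001ULL + (uint64_t)run);
    int mutant = (int)(rng.unif() * N);
    if (mutant >= N) mutant = N - 1;
    sim.reset_single(mutant);
    double events = 0.0;
    while (sim.n_coop > 0 && sim.n_coop < N) {
      int upd = sim.pick_updater(rng, cum);
      if (collect_q) {
        double nc = 0.0, kc = 0.0, nd = 0.0, kd = 0.0;
        for (int i = 0; i < N; ++i) {
          if (sim.x[i]) { nc += sim.ncoop[i]; kc += g.deg[i]; }
          else          { nd += sim.ncoop[i]; kd += g.deg[i]; }
        }
        qc_sum += nc / kc;
        qd_sum += nd / kd;
        n_coex += 1.0;
        // interface statistic around the updating node
        // leaves have no neighbour besides the updater, so they carry no
        // conditional frequency and are skipped
        double sc = 0.0, sd = 0.0;
        int ncnt = 0, dcnt = 0;
        for (int t = g.start[upd]; t < g.start[upd + 1]; ++t) {
          int v = g.nb[t];
          if (g.deg[v] < 2) continue;
          double frac = (sim.ncoop[v] - sim.x[upd]) / (g.deg[v] - 1.0);
          if (sim.x[v]) { sc += frac; ++ncnt; }
          else          { sd += frac; ++dcnt; }
        }
        if (ncnt > 0 && dcnt > 0) {
          ic_sum += sc / ncnt;
          id_sum += sd / dcnt;
          n_iface += 1.0;
          for (int t = g.start[upd]; t < g.start[upd + 1]; ++t) {
            int v = g.nb[t];
            int kv = (int)g.deg[v];
            if (kv < 2) continue;
            double frac = (sim.ncoop[v] - sim.x[upd]) / (g.deg[v] - 1.0);
            if (sim.x[v]) { cls_c[kv] += frac; cls_cn[kv] += 1.0; }
            else          { cls_d[kv] += frac; cls_dn[kv] += 1.0; }
          }
        }
      }
      sim.imitate(upd, rng, b, c, delta);
      events += 1.0;
      if (events > event_budget) {
        stop("event budget (%g) exceeded in run %d", event_budget, run + 1);
      }
    }
    total_events += events;
    if (sim.n_coop == N) ++n_fix;
  }
  List cls = R_NilValue;
  if (collect_q) {
    NumericMatrix deg_cls(max_deg + 1, 4);
    for (int k = 0; k <= max_deg; ++k) {
      deg_cls(k, 0) = cls_cn[k];
      deg_cls(k, 1) = cls_cn[k] > 0 ? cls_c[k] / cls_cn[k] : NA_REAL;
      deg_cls(k, 2) = cls_dn[k];
      deg_cls(k, 3) = cls_dn[k] > 0 ? cls_d[k] / cls_dn[k] : NA_REAL;
    }
    cls = List::create(_["degree_classes"] = deg_cls);
  }
  return List::create(
    _["n_fix_C"] = (double)n_fix,
    _["mean_events"] = total_events / n_runs,
    _["q_CC"] = collect_q ? ic_sum / n_iface : NA_REAL,
    _["q_CD"] = collect_q ? id_sum / n_iface : NA_REAL,
    _["n_interface_events"] = n_iface,
    _["q_CC_global"] = collect_q ? qc_sum / n_coex : NA_REAL,
    _["q_CD_global"] = collect_q ? qd_sum / n_coex : NA_REAL,
    _["n_coex_events"] = n_coex,
    _["extras"] = cls
  );
}

// [[Rcpp::export(name = ".sim_longterm_cpp")]]
List sim_longterm_cpp(IntegerMatrix edges, int N, NumericVector probs,
                      double b, double c, double delta, double u,
                      double n_events, double seed, int start_all) {
  Graph g = make_graph(edges, N);
  std::vector<double> cum = cum_from_probs(probs);
  Sim sim(g);
  Xoshiro rng((uint64_t)seed * 0x100000001ULL + 0x9E3779B9ULL);
  if (start_all >= 0) {
    sim.reset_all(start_all);
  } else {
    int mutant = (int)(rng.unif() * N);
    sim.reset_all(0);
    sim.set_strategy(mutant >= N ? N - 1 : mutant, 1);
  }
  std::vector<double> pay(N, 0.0);
  double events_in_C = 0.0, events_in_D = 0.0;
  for (double e = 0; e < n_events; e += 1.0) {
    bool absorbing = (sim.n_coop == 0 || sim.n_coop == N);
    if (absorbing) {
      if (sim.n_coop == N) events_in_C += 1.0; else events_in_D += 1.0;
      if (u > 0.0 && rng.unif() < u) {
        int m = (int)(rng.unif() * N);
        if (m >= N) m = N - 1;
        sim.set_strategy(m, 1 - sim.x[m]);
      }
    } else {
      sim.step(rng, cum, b, c, delta);
    }
    for (int i = 0; i < N; ++i) pay[i] += sim.payoff(i, b, c);
  }
  NumericVector mean_pay(N);
  for (int i = 0; i < N; ++i) mean_pay[i] = pay[i] / n_events;
  return List::create(
    _["mean_payoff"] = mean_pay,
    _["frac_all_C"] = events_in_C / n_events,
    _["frac_all_D"] = events_in_D / n_events
  );
}
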