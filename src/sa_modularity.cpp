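#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Weighted modularity over a bipartite carrier. With z the module assignment
// of row nodes (0..nr-1) and column nodes (nr..nr+nc-1):
//   Q = (1/W) * sum_{ij, z_i == z_j} A_ij  -  (1/W^2) * sum_s Sr_s * Sc_s
// where Sr_s / Sc_s are the summed row / column marginal totals of module s.
// On a bipartite incidence viewed as a directed prey->predator graph the
// directed unipartite objective reduces to the same expression, so a single
// engine serves both objectives.

namespace {

struct Net {
  int nr, nc, n;
  double W;
  std::vector<double> r, c;                 // marginal totals
  std::vector<std::vector<int>> nb;         // neighbour indices (global ids)
  std::vector<std::vector<double>> nw;      // neighbour weights
};

Net build_net(const NumericMatrix& A) {
  Net net;
  net.nr = A.nrow();
  net.nc = A.ncol();
  net.n = net.nr + net.nc;
  net.W = 0.0;
  net.r.assign(net.nr, 0.0);
  net.c.assign(net.nc, 0.0);
  net.nb.assign(net.n, {});
  net.nw.assign(net.n, {});
  for (int i = 0; i < net.nr; ++i) {
    for (int j = 0; j < net.nc; ++j) {
      double w = A(i, j);
      if (w > 0) {
        net.r[i] += w;
        net.c[j] += w;
        net.W += w;
        net.nb[i].push_back(net.nr + j);
        net.nw[i].push_back(w);
        net.nb[net.nr + j].push_back(i);
        net.nw[net.nr + j].push_back(w);
      }
    }
  }
  return net;
}

struct State {
  std::vector<int> z;
  std::vector<double> Sr, Sc;
  std::vector<int> size;
  double intra;  // sum of intra-module edge weight

  void init(const Net& net, const std::vector<int>& assign) {
    z = assign;
    Sr.assign(net.n, 0.0);
    Sc.assign(net.n, 0.0);
    size.assign(net.n, 0);
    intra = 0.0;
    for (int i = 0; i < net.nr; ++i) { Sr[z[i]] += net.r[i]; size[z[i]]++; }
    for (int j = 0; j < net.nc; ++j) { Sc[z[net.nr + j]] += net.c[j]; size[z[net.nr + j]]++; }
    for (int i = 0; i < net.nr; ++i)
      for (size_t k = 0; k < net.nb[i].size(); ++k)
        if (z[i] == z[net.nb[i][k]]) intra += net.nw[i][k];
  }

  double q(const Net& net) const {
    double null_part = 0.0;
    for (int s = 0; s < net.n; ++s) null_part += Sr[s] * Sc[s];
    return intra / net.W - null_part / (net.W * net.W);
  }

  // change in Q if node v moves from its module to module t
  double move_dq(const Net& net, int v, int t) const {
    int s = z[v];
    if (s == t) return 0.0;
    double k_s = 0.0, k_t = 0.0;
    for (size_t k = 0; k < net.nb[v].size(); ++k) {
      int zm = z[net.nb[v][k]];
      if (zm == s) k_s += net.nw[v][k];
      else if (zm == t) k_t += net.nw[v][k];
    }
    double strength_term;
    if (v < net.nr) strength_term = net.r[v] * (Sc[t] - Sc[s]);
    else            strength_term = net.c[v - net.nr] * (Sr[t] - Sr[s]);
    return (k_t - k_s) / net.W - strength_term / (net.W * net.W);
  }

  void apply_move(const Net& net, int v, int t) {
    int s = z[v];
    double k_s = 0.0, k_t = 0.0;
    for (size_t k = 0; k < net.nb[v].size(); ++k) {
      int zm = z[net.nb[v][k]];
      if (zm == s) k_s += net.nw[v][k];
      else if (zm == t) k_t += net.nw[v][k];
    }
    intra += k_t - k_s;
    if (v < net.nr) { Sr[s] -= net.r[v]; Sr[t] += net.r[v]; }
    else            { Sc[s] -= net.c[v - net.nr]; Sc[t] += net.c[v - net.nr]; }
    size[s]--; size[t]++;
    z[v] = t;
  }

  double merge_dq(const Net& net, int s, int t) const {
    double cross = 0.0;
    for (int i = 0; i < net.nr; ++i) {
      if (z[i] != s && z[i] != t) continue;
      for (size_t k = 0; k < net.nb[i].size(); ++k) {
        int zc = z[net.nb[i][k]];
        if ((z[i] == s && zc == t) || (z[i] == t && zc == s)) cross += net.nw[i][k];
      }
    }
    return cross / net.W - (Sr[s] * Sc[t] + Sr[t] * Sc[s]) / (net.W * net.W);
  }

  void apply_merge(const Net& net, int s, int t) {
    // merge t into s
    for (int i = 0; i < net.nr; ++i)
      if (z[i] == t)
        for (size_t k = 0; k < net.nb[i].size(); ++k)
          if (z[net.nb[i][k]] == s) intra += net.nw[i][k];
    for (int i = 0; i < net.nr; ++i)
      if (z[i] == s)
        for (size_t k = 0; k < net.nb[i].size(); ++k)
          if (z[net.nb[i][k]] == t) intra += net.nw[i][k];
    Sr[s] += Sr[t]; Sr[t] = 0.0;
    Sc[s] += Sc[t]; Sc[t] = 0.0;
    size[s] += size[t]; size[t] = 0;
    for (int v = 0; v < (int)z.size(); ++v) if (z[v] == t) z[v] = s;
  }

  int empty_slot() const {
    for (int s = 0; s < (int)size.size(); ++s) if (size[s] == 0) return s;
    return -1;
  }
};

int runif_int(int n) {
  int k = (int)std::floor(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// greedy passes: best single-node move (incl. empty module), then greedy
// merges, until neither improves
void local_optimize(const Net& net, State& st) {
  const double eps = 1e-13;
  bool improved = true;
  while (improved) {
    improved = false;
    bool moved = true;
    while (moved) {
      moved = false;
      for (int v = 0; v < net.n; ++v) {
        int best_t = -1;
        double best_dq = eps;
        int emp = st.empty_slot();
        for (int t = 0; t < net.n; ++t) {
          if (st.size[t] == 0 && t != emp) continue;
          if (t == st.z[v]) continue;
          double dq = st.move_dq(net, v, t);
          if (dq > best_dq) { best_dq = dq; best_t = t; }
        }
        if (best_t >= 0) { st.apply_move(net, v, best_t); moved = true; improved = true; }
      }
    }
    // greedy merge of the best-improving module pair
    bool merged = true;
    while (merged) {
      merged = false;
      std::vector<int> mods;
      for (int s = 0; s < net.n; ++s) if (st.size[s] > 0) mods.push_back(s);
      double best_dq = eps;
      int bs = -1, bt = -1;
      for (size_t a = 0; a < mods.size(); ++a)
        for (size_t b = a + 1; b < mods.size(); ++b) {
          double dq = st.merge_dq(net, mods[a], mods[b]);
          if (dq > best_dq) { best_dq = dq; bs = mods[a]; bt = mods[b]; }
        }
      if (bs >= 0) { st.apply_merge(net, bs, bt); merged = true; improved = true; }
    }
  }
}

} // namespace

// [[Rcpp::export]]
List sa_partition(NumericMatrix A, bool anneal = true, double cooling = 0.995,
                  double merge_prob = 0.1, int max_sweeps = 5000) {
  Net net = build_net(A);
  State st;
  std::vector<int> init(net.n);
  for (int v = 0; v < net.n; ++v) init[v] = v;  // singleton start
  st.init(net, init);

  if (anneal && net.n > 1) {
    // initial temperature from move-acceptance calibration
    double sum_abs = 0.0;
    int n_cal = 100;
    for (int k = 0; k < n_cal; ++k) {
      int v = runif_int(net.n);
      int t = runif_int(net.n);
      if (t != st.z[v]) sum_abs += std::fabs(st.move_dq(net, v, t));
    }
    double T = 2.0 * sum_abs / n_cal;
    if (T <= 0) T = 1e-3;
    const double T_min = T * 1e-6;

    State best = st;
    double best_q = st.q(net);
    long consec_rej = 0;
    const long rej_limit = (long)net.n * (long)net.n;

    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      for (int step = 0; step < net.n; ++step) {
        bool accepted = false;
        if (unif_rand() < merge_prob) {
          std::vector<int> mods;
          for (int s = 0; s < net.n; ++s) if (st.size[s] > 0) mods.push_back(s);
          if (mods.size() >= 2) {
            int a = runif_int(mods.size());
            int b = runif_int(mods.size() - 1);
            if (b >= a) b++;
            double dq = st.merge_dq(net, mods[a], mods[b]);
            if (dq > 0 || unif_rand() < std::exp(dq / T)) {
              st.apply_merge(net, mods[a], mods[b]);
              accepted = true;
            }
          }
        } else {
          int v = runif_int(net.n);
          int t;
          if (unif_rand() < 0.1) {
            t = st.empty_slot();
            if (t < 0) t = runif_int(net.n);
          } else {
            t = runif_int(net.n);
          }
          if (t != st.z[v]) {
            double dq = st.move_dq(net, v, t);
            if (dq > 0 || unif_rand() < std::exp(dq / T)) {
              st.apply_move(net, v, t);
              accepted = true;
            }
          }
        }
        if (accepted) {
          consec_rej = 0;
          double q = st.q(net);
          if (q > best_q) { best_q = q; best = st; }
        } else {
          consec_rej++;
        }
      }
      T *= cooling;
      if (consec_rej > rej_limit || T < T_min) break;
    }
    st = best;
  } else if (net.n > 1) {
    // random initial grouping for the label-propagation-style route
    int k = 2 + runif_int(std::max(1, net.n / 2));
    std::vector<int> rnd(net.n);
    for (int v = 0; v < net.n; ++v) rnd[v] = runif_int(k);
    st.init(net, rnd);
  }

  local_optimize(net, st);

  IntegerVector out(net.n);
  for (int v = 0; v < net.n; ++v) out[v] = st.z[v];
  return List::create(_["assignment"] = out, _["q"] = st.q(net));
}
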