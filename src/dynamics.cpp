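#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sparse adjacency is passed as the CSC slots of a dgCMatrix whose entry
// (i, j) is w_ij, the weight of the connection from node j to node i.
// Column j therefore lists the out-targets of node j, which is exactly the
// scatter order needed when node j is active.

// ---------------------------------------------------------------------------
// Greenberg-Hastings three-state automaton
// states: 0 = inactive (I), 1 = active (A), 2 = refractory (R)
// Synchronous update against the start-of-step state:
//   A -> R always; R -> I with prob r2;
//   I -> A if sum of active in-neighbor weights > threshold (strict),
//          else with prob r1.
// Uses R's RNG stream (seed at the R level).
// [[Rcpp::export]]
List cpp_run_gh(IntegerVector adj_p, IntegerVector adj_i, NumericVector adj_x,
                int n, double threshold, double r1, double r2,
                int t_max, int t_init, IntegerVector init_active,
                bool keep_raw) {
  if (t_max <= t_init) stop("t_max must exceed t_init");
  int t_sim = t_max - t_init;
  IntegerMatrix raster(n, t_sim);              // conflated {0,1}
  IntegerMatrix raw = keep_raw ? IntegerMatrix(n, t_sim) : IntegerMatrix(0, 0);

  std::vector<int> state(n, 0), next(n, 0);
  for (int k = 0; k < init_active.size(); ++k) state[init_active[k]] = 1;
  std::vector<double> input(n, 0.0);

  for (int t = 0; t < t_max; ++t) {
    std::fill(input.begin(), input.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      if (state[j] != 1) continue;
      for (int k = adj_p[j]; k < adj_p[j + 1]; ++k) input[adj_i[k]] += adj_x[k];
    }
    for (int i = 0; i < n; ++i) {
      int s = state[i];
      if (s == 1) {
        next[i] = 2;
      } else if (s == 2) {
        next[i] = (unif_rand() < r2) ? 0 : 2;
      } else {
        if (input[i] > threshold) next[i] = 1;
        else next[i] = (unif_rand() < r1) ? 1 : 0;
      }
    }
    std::swap(state, next);
    if (t >= t_init) {
      int col = t - t_init;
      for (int i = 0; i < n; ++i) {
        raster(i, col) = (state[i] == 1) ? 1 : 0;
        if (keep_raw) raw(i, col) = state[i];
      }
    }
  }
  return List::create(_["raster"] = raster, _["raw"] = raw);
}

// ---------------------------------------------------------------------------
// Metropolis single-spin-flip Ising dynamics on a binary adjacency pattern.
// One sweep = n proposals; site chosen uniformly at random (or sequentially),
// flip accepted with probability min(exp(-dE / T), 1), where
// dE = 2 * J * s_i * sum_{neighbors} s_j (each unordered bond counted once
// in the energy).
// dE = 2*J*s_i*nb with nb an integer in [-deg, deg]; acceptance factors
// exp(-2*J*k/T) are tabulated per k = s_i * nb up to the maximum degree.
static inline void metro_sweep(std::vector<int>& s,
                               const IntegerVector& adj_p,
                               const IntegerVector& adj_i,
                               int n, double temperature, double J,
                               bool sequential,
                               const std::vector<double>& acc) {
  for (int k = 0; k < n; ++k) {
    int site = sequential ? k : (int)(unif_rand() * n);
    if (site >= n) site = n - 1;
    int nb = 0;
    for (int e = adj_p[site]; e < adj_p[site + 1]; ++e) nb += s[adj_i[e]];
    int prod = s[site] * nb;  // dE = 2*J*prod
    if (prod <= 0 || unif_rand() < acc[prod]) s[site] = -s[site];
  }
}

static std::vector<double> acceptance_table(const IntegerVector& adj_p, int n,
                                            double temperature, double J) {
  int max_deg = 0;
  for (int i = 0; i < n; ++i)
    max_deg = std::max(max_deg, adj_p[i + 1] - adj_p[i]);
  std::vector<double> acc(max_deg + 1, 1.0);
  for (int k = 1; k <= max_deg; ++k)
    acc[k] = std::exp(-2.0 * J * k / temperature);
  return acc;
}

// [[Rcpp::export]]
IntegerMatrix cpp_run_ising(IntegerVector adj_p, IntegerVector adj_i,
                            int n, double temperature, double J,
                            int t_max, int t_init, IntegerVector init_spins,
                            bool sequential) {
  if (t_max <= t_init) stop("t_max must exceed t_init");
  if (temperature <= 0) stop("temperature must be positive");
  int t_sim = t_max - t_init;
  std::vector<int> s(init_spins.begin(), init_spins.end());
  std::vector<double> acc = acceptance_table(adj_p, n, temperature, J);
  IntegerMatrix raster(n, t_sim);
  for (int t = 0; t < t_max; ++t) {
    metro_sweep(s, adj_p, adj_i, n, temperature, J, sequential, acc);
    if (t >= t_init) {
      int col = t - t_init;
      for (int i = 0; i < n; ++i) raster(i, col) = s[i];
    }
  }
  return raster;
}

// [[Rcpp::export]]
IntegerVector cpp_metropolis_sweeps(IntegerVector spins,
                                    IntegerVector adj_p, IntegerVector adj_i,
                                    int n_sweeps, double temperature, double J,
                                    bool sequential) {
  int n = spins.size();
  std::vector<int> s(spins.begin(), spins.end());
  std::vector<double> acc = acceptance_table(adj_p, n, temperature, J);
  for (int t = 0; t < n_sweeps; ++t)
    metro_sweep(s, adj_p, adj_i, n, temperature, J, sequential, acc);
  return IntegerVector(s.begin(), s.end());
}

// ---------------------------------------------------------------------------
// Union-find cluster labeling.
// mode: 0 = active_only (clusters of state == 1),
//       1 = same_value (clusters of equal state values).
// adjacency: symmetric binary support pattern (CSC of w_ij + w_ji > 0).

struct UF {
  std::vector<int> parent, sz;
  UF(int n) : parent(n), sz(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (sz[a] < sz[b]) std::swap(a, b);
    parent[b] = a; sz[a] += sz[b];
  }
};

// Cluster sizes of one state vector, descending. `mask` (may be empty)
// restricts to an induced subgraph.
static std::vector<int> cluster_sizes_one(const int* state,
                                          const IntegerVector& adj_p,
                                          const IntegerVector& adj_i,
                                          int n, int mode,
                                          const std::vector<char>& mask) {
  bool use_mask = !mask.empty();
  UF uf(n);
  for (int j = 0; j < n; ++j) {
    if (use_mask && !mask[j]) continue;
    if (mode == 0 && state[j] != 1) continue;
    for (int e = adj_p[j]; e < adj_p[j + 1]; ++e) {
      int i = adj_i[e];
      if (i >= j) continue;  // symmetric pattern: each edge once
      if (use_mask && !mask[i]) continue;
      if (mode == 0) {
        if (state[i] == 1) uf.unite(i, j);
      } else {
        if (state[i] == state[j]) uf.unite(i, j);
      }
    }
  }
  std::vector<int> count(n, 0);
  for (int i = 0; i < n; ++i) {
    if (use_mask && !mask[i]) continue;
    if (mode == 0 && state[i] != 1) continue;
    ++count[uf.find(i)];
  }
  std::vector<int> sizes;
  for (int i = 0; i < n; ++i) if (count[i] > 0) sizes.push_back(count[i]);
  std::sort(sizes.begin(), sizes.end(), std::greater<int>());
  return sizes;
}

// [[Rcpp::export]]
IntegerVector cpp_cluster_sizes(IntegerVector state,
                                IntegerVector adj_p, IntegerVector adj_i,
                                int mode, IntegerVector subset) {
  int n = state.size();
  std::vector<char> mask;
  if (subset.size() > 0) {
    mask.assign(n, 0);
    for (int k = 0; k < subset.size(); ++k) mask[subset[k]] = 1;
  }
  std::vector<int> sizes =
      cluster_sizes_one(&state[0], adj_p, adj_i, n, mode, mask);
  return IntegerVector(sizes.begin(), sizes.end());
}

// Per-time-step two largest cluster sizes over a raster (n x t_sim).
// Union-find buffers are reused across steps.
// [[Rcpp::export]]
IntegerMatrix cpp_two_largest_series(IntegerMatrix raster,
                                     IntegerVector adj_p, IntegerVector adj_i,
                                     int mode, IntegerVector subset) {
  int n = raster.nrow(), t_sim = raster.ncol();
  std::vector<char> mask;
  bool use_mask = subset.size() > 0;
  if (use_mask) {
    mask.assign(n, 0);
    for (int k = 0; k < subset.size(); ++k) mask[subset[k]] = 1;
  }
  IntegerMatrix out(t_sim, 2);
  UF uf(n);
  std::vector<int> count(n);
  for (int t = 0; t < t_sim; ++t) {
    const int* state = &raster(0, t);
    for (int i = 0; i < n; ++i) { uf.parent[i] = i; uf.sz[i] = 1; }
    for (int j = 0; j < n; ++j) {
      if (use_mask && !mask[j]) continue;
      if (mode == 0 && state[j] != 1) continue;
      for (int e = adj_p[j]; e < adj_p[j + 1]; ++e) {
        int i = adj_i[e];
        if (i >= j) continue;
        if (use_mask && !mask[i]) continue;
        if (mode == 0 ? (state[i] == 1) : (state[i] == state[j])) uf.unite(i, j);
      }
    }
    std::fill(count.begin(), count.end(), 0);
    for (int i = 0; i < n; ++i) {
      if (use_mask && !mask[i]) continue;
      if (mode == 0 && state[i] != 1) continue;
      ++count[uf.find(i)];
    }
    int s1 = 0, s2 = 0;
    for (int i = 0; i < n; ++i) {
      int c = count[i];
      if (c > s1) { s2 = s1; s1 = c; }
      else if (c > s2) { s2 = c; }
    }
    out(t, 0) = s1;
    out(t, 1) = s2;
  }
  return out;
}
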