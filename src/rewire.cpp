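#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

// Degree-preserving randomization by repeated double-edge swaps:
// pick edges {a,b} and {c,d}, replace with {a,d} and {c,b} unless the swap
// would create a self-loop or a duplicate edge, in which case it is
// rejected and counted as an attempt. Every node keeps its exact degree.
//
// A self-contained xorshift128+ generator (seeded via splitmix64) makes
// null streams reproducible from an integer seed, independently of R's
// global RNG state. Edge existence is tracked in per-node unsorted
// adjacency vectors with swap-and-pop removal: degrees are small in sparse
// interactomes, so a short linear scan beats hashing here.

namespace {

struct Xorshift128 {
  uint64_t s0, s1;
  explicit Xorshift128(uint64_t seed) {
    auto next = [&seed]() {
      seed += 0x9E3779B97F4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      return z ^ (z >> 31);
    };
    s0 = next();
    s1 = next();
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform in [0, m): Lemire multiply-shift (bias < m / 2^64, negligible)
  uint32_t below(uint32_t m) {
    return (uint32_t)(((unsigned __int128)next() * m) >> 64);
  }
  bool coin() { return (next() & 1ULL) != 0; }
};

struct AdjGraph {
  std::vector<std::vector<int>> adj;
  void build(const std::vector<int>& ea, const std::vector<int>& eb, int n) {
    adj.assign(n, {});
    for (size_t i = 0; i < ea.size(); ++i) {
      adj[ea[i]].push_back(eb[i]);
      adj[eb[i]].push_back(ea[i]);
    }
  }
  bool has(int u, int v) const {
    for (int w : adj[u]) {
      if (w == v) return true;
    }
    return false;
  }
  void insert(int u, int v) { adj[u].push_back(v); }
  void remove(int u, int v) {
    std::vector<int>& a = adj[u];
    for (size_t k = 0; k < a.size(); ++k) {
      if (a[k] == v) {
        a[k] = a.back();
        a.pop_back();
        return;
      }
    }
  }
};

void swap_pass(std::vector<int>& ea, std::vector<int>& eb, AdjGraph& g,
               long attempts, Xorshift128& rng) {
  const uint32_t m = (uint32_t)ea.size();
  if (m < 2) return;
  for (long t = 0; t < attempts; ++t) {
    uint32_t i = rng.below(m);
    uint32_t j = rng.below(m);
    if (i == j) continue;
    int a = ea[i], b = eb[i];
    int c = ea[j], d = eb[j];
    if (rng.coin()) std::swap(c, d); // random orientation of second edge
    // propose {a,d} and {c,b}
    if (a == d || c == b) continue;
    if (g.has(a, d) || g.has(c, b)) continue;
    g.remove(a, b); g.remove(b, a);
    g.remove(c, d); g.remove(d, c);
    g.insert(a, d); g.insert(d, a);
    g.insert(c, b); g.insert(b, c);
    ea[i] = a; eb[i] = d;
    ea[j] = c; eb[j] = b;
  }
}

} // namespace

// [[Rcpp::export(name = ".rewire_edges_cpp")]]
Rcpp::IntegerMatrix rewire_edges_cpp(Rcpp::IntegerMatrix edges, int n_genes,
                                     double attempts, double seed) {
  const int m = edges.nrow();
  std::vector<int> ea(m), eb(m);
  for (int i = 0; i < m; ++i) {
    ea[i] = edges(i, 0);
    eb[i] = edges(i, 1);
  }
  AdjGraph g;
  g.build(ea, eb, n_genes);
  Xorshift128 rng((uint64_t)seed);
  swap_pass(ea, eb, g, (long)attempts, rng);
  Rcpp::IntegerMatrix out(m, 2);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = std::min(ea[i], eb[i]);
    out(i, 1) = std::max(ea[i], eb[i]);
  }
  return out;
}

// For each of n_perm independent null networks (each rewired afresh from
// the observed edges), count edges with one endpoint in A and the other in
// B. Membership vectors are 0/1 ints over gene indices. When stop_exceed
// > 0, generation halts early once that many null counts >= obs_count have
// been seen: the add-one p-value can then no longer fall below the caller's
// threshold, so the accept/reject decision is already final (the null
// stream is unchanged, merely truncated). Unused tail entries are NA.
// [[Rcpp::export(name = ".gsla_null_counts_cpp")]]
Rcpp::IntegerVector gsla_null_counts_cpp(Rcpp::IntegerMatrix edges,
                                         int n_genes,
                                         Rcpp::IntegerVector in_a,
                                         Rcpp::IntegerVector in_b,
                                         int n_perm, double attempts,
                                         double seed, int obs_count = 0,
                                         int stop_exceed = 0) {
  const int m = edges.nrow();
  std::vector<int> ea0(m), eb0(m);
  for (int i = 0; i < m; ++i) {
    ea0[i] = edges(i, 0);
    eb0[i] = edges(i, 1);
  }
  Rcpp::IntegerVector out(n_perm);
  Xorshift128 rng((uint64_t)seed);
  std::vector<int> ea(m), eb(m);
  AdjGraph g;
  int exceed = 0;
  for (int p = 0; p < n_perm; ++p) {
    ea = ea0;
    eb = eb0;
    g.build(ea, eb, n_genes);
    swap_pass(ea, eb, g, (long)attempts, rng);
    int count = 0;
    for (int i = 0; i < m; ++i) {
      int u = ea[i], v = eb[i];
      if ((in_a[u] && in_b[v]) || (in_a[v] && in_b[u])) ++count;
    }
    out[p] = count;
    if (stop_exceed > 0) {
      if (count >= obs_count) ++exceed;
      if (exceed >= stop_exceed) {
        for (int q = p + 1; q < n_perm; ++q) out[q] = NA_INTEGER;
        break;
      }
    }
    if ((p & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
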