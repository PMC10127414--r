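// Binary-graph metrics and the covariance-network permutation engine.
//
// Graphs are undirected, unweighted, at most 64 nodes, held as per-node
// 64-bit adjacency masks so that neighbourhood intersections (clustering),
// BFS frontiers (distances) and double-edge swaps are a handful of word
// operations.  The permutation engine re-runs the whole chain
// correlation -> negative zeroing -> sparsity binarization -> metrics ->
// random-network normalization -> AUC for every relabelling, so it must
// stay allocation-free in the inner loop.

// The permutation engine spends its time in the swap/BFS inner loops; make
// sure they are compiled at full optimization even when the site-wide
// CXXFLAGS end in a lower level.
#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3")
#endif

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const int MAXN = 64;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded from R's RNG stream, so set.seed() governs all
// randomness (rewiring, permutation relabelling) deterministically.
// ---------------------------------------------------------------------------
struct Xoshiro {
  uint64_t s[4];
  static inline uint64_t rotl(const uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform integer in [0, m); m is tiny (<= a few thousand), modulo bias
  // of the top 32 bits is < 2^-20 and irrelevant here
  inline uint32_t below(uint32_t m) {
    return (uint32_t)((next() >> 32) % (uint64_t)m);
  }
  void seed_from_R() {
    uint64_t any = 0;
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(i + 1));
      any |= s[i];
    }
    if (!any) s[0] = 0x106689D45497FDB5ULL;
    for (int i = 0; i < 16; ++i) next();
  }
};

// ---------------------------------------------------------------------------
// Graph container
// ---------------------------------------------------------------------------
struct BitGraph {
  int n;
  uint64_t row[MAXN];
  void clear(int n_) { n = n_; std::memset(row, 0, sizeof(row)); }
  inline void add(int i, int j) { row[i] |= 1ULL << j; row[j] |= 1ULL << i; }
  inline void del(int i, int j) {
    row[i] &= ~(1ULL << j); row[j] &= ~(1ULL << i);
  }
  inline bool has(int i, int j) const { return (row[i] >> j) & 1ULL; }
  inline int deg(int i) const { return __builtin_popcountll(row[i]); }
};

static BitGraph as_bitgraph(const NumericMatrix& adj) {
  int n = adj.nrow();
  if (n != adj.ncol()) stop("adjacency matrix must be square");
  if (n > MAXN) stop("graphs with more than 64 nodes are not supported");
  BitGraph g; g.clear(n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (adj(i, j) != 0.0) {
        if (i == j) stop("adjacency matrix must have a zero diagonal");
        g.row[i] |= 1ULL << j;
      }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (g.has(i, j) != g.has(j, i)) stop("adjacency matrix must be symmetric");
  return g;
}

// BFS from s restricted to nodes of 'mask'; dist must be preset to -1 for
// every node of mask (other entries are ignored)
static inline void bfs_mask(const BitGraph& g, int s, uint64_t mask, int* dist) {
  uint64_t visited = 1ULL << s;
  uint64_t frontier = visited;
  dist[s] = 0;
  int d = 0;
  while (frontier) {
    uint64_t nxt = 0, f = frontier;
    while (f) { int v = __builtin_ctzll(f); f &= f - 1; nxt |= g.row[v]; }
    nxt &= mask & ~visited;
    ++d;
    uint64_t t = nxt;
    while (t) { int v = __builtin_ctzll(t); t &= t - 1; dist[v] = d; }
    visited |= nxt;
    frontier = nxt;
  }
}

// ---------------------------------------------------------------------------
// Metrics
// ---------------------------------------------------------------------------

// per-node clustering coefficient; nodes with degree < 2 contribute 0
static double clustering_nodes(const BitGraph& g, double* cp /*nullable*/) {
  double sum = 0.0;
  for (int i = 0; i < g.n; ++i) {
    int d = g.deg(i);
    double c = 0.0;
    if (d >= 2) {
      uint64_t nb = g.row[i], t = nb;
      long links2 = 0;  // twice the number of edges among neighbours
      while (t) {
        int j = __builtin_ctzll(t); t &= t - 1;
        links2 += __builtin_popcountll(g.row[j] & nb);
      }
      c = (double)links2 / ((double)d * (d - 1));
    }
    if (cp) cp[i] = c;
    sum += c;
  }
  return g.n ? sum / g.n : NA_REAL;
}

struct PathStats {
  double lp;              // mean shortest path over finite unordered pairs
  double eglobal;         // mean of 1/d over all unordered pairs (1/inf = 0)
  long finite_pairs;
  long unreachable_pairs; // unordered pairs with no path
};

static PathStats path_stats(const BitGraph& g, double* nodal_eff /*nullable*/) {
  PathStats ps; ps.lp = NA_REAL; ps.eglobal = 0.0;
  ps.finite_pairs = 0; ps.unreachable_pairs = 0;
  int n = g.n;
  uint64_t full = (n == 64) ? ~0ULL : ((1ULL << n) - 1);
  long sumd = 0;
  double suminv_pairs = 0.0;
  int dist[MAXN];
  for (int s = 0; s < n; ++s) {
    for (int i = 0; i < n; ++i) dist[i] = -1;
    bfs_mask(g, s, full, dist);
    double acc = 0.0;
    for (int t = 0; t < n; ++t) {
      if (t == s) continue;
      if (dist[t] > 0) {
        acc += 1.0 / dist[t];
        if (t > s) { sumd += dist[t]; ++ps.finite_pairs; suminv_pairs += 1.0 / dist[t]; }
      } else if (t > s) {
        ++ps.unreachable_pairs;
      }
    }
    if (nodal_eff) nodal_eff[s] = (n > 1) ? acc / (n - 1) : 0.0;
  }
  if (ps.finite_pairs > 0) ps.lp = (double)sumd / ps.finite_pairs;
  long pairs = (long)n * (n - 1) / 2;
  ps.eglobal = pairs ? suminv_pairs / pairs : 0.0;
  return ps;
}

// local efficiency of each node: global efficiency of the subgraph induced
// by its neighbours (0 when fewer than 2 neighbours)
static double local_eff_nodes(const BitGraph& g, double* el /*nullable*/) {
  double sum = 0.0;
  int dist[MAXN];
  for (int i = 0; i < g.n; ++i) {
    uint64_t mask = g.row[i];
    int k = __builtin_popcountll(mask);
    double e = 0.0;
    if (k >= 2) {
      double suminv = 0.0;
      uint64_t src = mask;
      while (src) {
        int s = __builtin_ctzll(src); src &= src - 1;
        uint64_t q = mask;
        while (q) { int v = __builtin_ctzll(q); q &= q - 1; dist[v] = -1; }
        bfs_mask(g, s, mask, dist);
        uint64_t u = mask & ~((s == 63) ? ~0ULL : ((1ULL << (s + 1)) - 1));
        while (u) {
          int v = __builtin_ctzll(u); u &= u - 1;
          if (dist[v] > 0) suminv += 1.0 / dist[v];
        }
      }
      e = suminv / ((double)k * (k - 1) / 2.0);
    }
    if (el) el[i] = e;
    sum += e;
  }
  return g.n ? sum / g.n : NA_REAL;
}

// Brandes betweenness, normalized by (n-1)(n-2)/2 for undirected graphs
static void betweenness_nodes(const BitGraph& g, double* bc) {
  int n = g.n;
  std::fill(bc, bc + n, 0.0);
  if (n < 3) return;
  int dist[MAXN], order[MAXN];
  double sigma[MAXN], delta[MAXN];
  uint64_t preds[MAXN];
  for (int s = 0; s < n; ++s) {
    for (int i = 0; i < n; ++i) {
      dist[i] = -1; sigma[i] = 0.0; delta[i] = 0.0; preds[i] = 0ULL;
    }
    dist[s] = 0; sigma[s] = 1.0;
    int head = 0, tail = 0;
    order[tail++] = s;
    while (head < tail) {
      int v = order[head++];
      uint64_t nb = g.row[v];
      while (nb) {
        int w = __builtin_ctzll(nb); nb &= nb - 1;
        if (dist[w] < 0) { dist[w] = dist[v] + 1; order[tail++] = w; }
        if (dist[w] == dist[v] + 1) { sigma[w] += sigma[v]; preds[w] |= 1ULL << v; }
      }
    }
    for (int i = tail - 1; i >= 1; --i) {
      int w = order[i];
      double coef = (1.0 + delta[w]) / sigma[w];
      uint64_t pm = preds[w];
      while (pm) {
        int v = __builtin_ctzll(pm); pm &= pm - 1;
        delta[v] += sigma[v] * coef;
      }
      bc[w] += delta[w];
    }
  }
  // each unordered pair was counted twice; normalize to a fraction
  double norm = (double)(n - 1) * (n - 2);
  for (int i = 0; i < n; ++i) bc[i] /= norm;
}

// ---------------------------------------------------------------------------
// Degree-preserving rewiring (Maslov-Sneppen double-edge swaps)
// ---------------------------------------------------------------------------
static long rewire_graph(BitGraph& g, int* ea, int* eb, int E,
                         long target, long max_attempts, Xoshiro& rng) {
  if (E < 2 || target <= 0) return 0;
  long swaps = 0, att = 0;
  uint64_t* row = g.row;
  const uint64_t uE = (uint64_t)E;
  while (swaps < target && att < max_attempts) {
    ++att;
    // one RNG draw per attempt: two edge indices (Lemire mapping of the two
    // 32-bit halves) and an orientation bit
    const uint64_t r = rng.next();
    const int e1 = (int)(((r & 0xFFFFFFFFULL) * uE) >> 32);
    const int e2 = (int)(((r >> 32) * uE) >> 32);
    if (e1 == e2) continue;
    int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
    if (r & 1ULL) { int t = c; c = d; d = t; }
    // propose (a,b),(c,d) -> (a,d),(c,b)
    if (a == d || c == b) continue;                       // self-loop
    if (((row[a] >> d) | (row[c] >> b)) & 1ULL) continue; // multi-edge
    row[a] = (row[a] & ~(1ULL << b)) | (1ULL << d);
    row[b] = (row[b] & ~(1ULL << a)) | (1ULL << c);
    row[c] = (row[c] & ~(1ULL << d)) | (1ULL << b);
    row[d] = (row[d] & ~(1ULL << c)) | (1ULL << a);
    ea[e1] = a; eb[e1] = d; ea[e2] = c; eb[e2] = b;
    ++swaps;
  }
  return swaps;
}

// Mean Cp and Lp over an ensemble of degree-preserving random networks.
// The ensemble is a single Maslov-Sneppen edge-swap Markov chain: the first
// member is recorded after a burn-in of swap_mult * E successful swaps from
// the observed graph, and each further member after swap_mult * E / 10
// additional successful swaps.  Marginally every member is a well-mixed
// degree-preserving randomization; members are correlated with each other,
// which leaves the ensemble mean unbiased and keeps the cost of large
// permutation runs linear in the burn-in rather than in n_random times it.
static void random_ensemble_means(const BitGraph& g, const int* ea, const int* eb,
                                  int E, int n_random, double swap_mult,
                                  double attempt_mult, Xoshiro& rng,
                                  double& mean_cp, double& mean_lp,
                                  bool need_cp = true) {
  double scp = 0.0, slp = 0.0;
  int lp_cnt = 0;
  long burn = (long)(swap_mult * E + 0.5);
  long spacing = (long)(swap_mult * E / 10.0 + 0.5);
  BitGraph h = g;
  int ca[2016], cb[2016];
  std::memcpy(ca, ea, sizeof(int) * E);
  std::memcpy(cb, eb, sizeof(int) * E);
  for (int r = 0; r < n_random; ++r) {
    long target = (r == 0) ? burn : spacing;
    long max_att = (long)(attempt_mult * (double)(target > 0 ? target : 1)) + 100;
    rewire_graph(h, ca, cb, E, target, max_att, rng);
    if (need_cp) scp += clustering_nodes(h, nullptr);
    PathStats ps = path_stats(h, nullptr);
    if (R_finite(ps.lp)) { slp += ps.lp; ++lp_cnt; }
  }
  mean_cp = (need_cp && n_random > 0) ? scp / n_random : NA_REAL;
  mean_lp = (lp_cnt > 0) ? slp / lp_cnt : NA_REAL;
}

// ---------------------------------------------------------------------------
// Correlation -> R+ -> sorted positive edges
// ---------------------------------------------------------------------------

// Pearson correlation of columns of X (n x p, column-major), upper triangle
// written into w[] in (i<j) enumeration order (i outer, j inner)
static void pearson_pairs(const double* X, int n, int p, double* z,
                          double* w) {
  // standardize each column into z
  for (int j = 0; j < p; ++j) {
    const double* col = X + (size_t)j * n;
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += col[i];
    m /= n;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = col[i] - m;
      ss += d * d;
    }
    if (ss <= 0.0) stop("constant volume column (node %d): correlation undefined", j + 1);
    double inv = 1.0 / std::sqrt(ss);
    double* zc = z + (size_t)j * n;
    for (int i = 0; i < n; ++i) zc[i] = (col[i] - m) * inv;
  }
  int idx = 0;
  for (int i = 0; i < p; ++i) {
    const double* zi = z + (size_t)i * n;
    for (int j = i + 1; j < p; ++j) {
      const double* zj = z + (size_t)j * n;
      double r = 0.0;
      for (int k = 0; k < n; ++k) r += zi[k] * zj[k];
      if (r > 1.0) r = 1.0;
      if (r < -1.0) r = -1.0;
      w[idx++] = r;
    }
  }
}

struct PairOrder {
  std::vector<int> pi, pj;     // endpoints in (i<j) enumeration order
  std::vector<int> ord;        // pair indices sorted: weight desc, then lex
  std::vector<double> w;       // zeroed weights (R+)
  int n_pos;                   // number of strictly positive weights
};

// stable sort by descending weight; enumeration order is lexicographic so
// stability gives the fixed (i,j) tie rule
static void order_pairs(PairOrder& po, int p) {
  int M = p * (p - 1) / 2;
  po.pi.resize(M); po.pj.resize(M); po.ord.resize(M);
  int idx = 0;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) { po.pi[idx] = i; po.pj[idx] = j; ++idx; }
  for (int k = 0; k < M; ++k) po.ord[k] = k;
  std::stable_sort(po.ord.begin(), po.ord.end(),
                   [&po](int a, int b) { return po.w[a] > po.w[b]; });
  po.n_pos = 0;
  for (int k = 0; k < M; ++k) if (po.w[po.ord[k]] > 0.0) ++po.n_pos;
}

static inline int k_at_sparsity(double s, int M) {
  return (int)std::floor(s * M + 1e-9);
}

// ---------------------------------------------------------------------------
// The full chain for one group of subjects
// ---------------------------------------------------------------------------
struct ChainOpts {
  int n_random;
  double swap_mult;
  double attempt_mult;
  bool do_norm;
  bool do_gamma;            // also track ensemble clustering (for Gamma)
  bool do_local;
  bool do_betw;
  bool do_nodal;
  bool reuse_denominators;  // use caller-supplied mean random Cp/Lp curves
};

enum GMetric { M_CP = 0, M_LP, M_EGLOB, M_ELOC, M_GAMMA, M_LAMBDA, M_SIGMA, NGM };

struct ChainOut {
  // curves: NGM x S global; p x S nodal (column-major: metric value for
  // node i at sparsity s at [s*p + i])
  std::vector<double> global;
  std::vector<double> nodal_eff, degree, betw;
  std::vector<int> requested_k, achieved_k;
  std::vector<long> unreachable;
  std::vector<double> mean_cp_rand, mean_lp_rand;
  void resize(int S, int p, bool do_nodal, bool do_betw) {
    global.assign((size_t)NGM * S, NA_REAL);
    requested_k.assign(S, 0); achieved_k.assign(S, 0);
    unreachable.assign(S, 0);
    mean_cp_rand.assign(S, NA_REAL); mean_lp_rand.assign(S, NA_REAL);
    if (do_nodal) {
      nodal_eff.assign((size_t)p * S, NA_REAL);
      degree.assign((size_t)p * S, NA_REAL);
    }
    if (do_betw) betw.assign((size_t)p * S, NA_REAL);
  }
};

// X: n x p column-major volumes of one group; spars must be increasing
static void run_chain(const double* X, int n, int p,
                      const double* spars, int S,
                      const ChainOpts& opt, Xoshiro& rng,
                      std::vector<double>& zbuf, PairOrder& po,
                      ChainOut& out,
                      const double* fixed_mcp = nullptr,
                      const double* fixed_mlp = nullptr) {
  int M = p * (p - 1) / 2;
  po.w.resize(M);
  pearson_pairs(X, n, p, zbuf.data(), po.w.data());
  for (int k = 0; k < M; ++k) if (po.w[k] < 0.0) po.w[k] = 0.0; // zero negatives
  order_pairs(po, p);

  out.resize(S, p, opt.do_nodal, opt.do_betw);

  BitGraph g; g.clear(p);
  int ea[2016], eb[2016];
  int have = 0;
  double cp_nodes_buf[MAXN], ne_buf[MAXN], bc_buf[MAXN];

  for (int s = 0; s < S; ++s) {
    int k_req = k_at_sparsity(spars[s], M);
    int k_eff = std::min(k_req, po.n_pos);
    while (have < k_eff) {
      int pr = po.ord[have];
      g.add(po.pi[pr], po.pj[pr]);
      ea[have] = po.pi[pr]; eb[have] = po.pj[pr];
      ++have;
    }
    out.requested_k[s] = k_req;
    out.achieved_k[s] = have;

    double cp = clustering_nodes(g, opt.do_nodal ? cp_nodes_buf : nullptr);
    PathStats ps = path_stats(g, opt.do_nodal ? ne_buf : nullptr);
    out.global[(size_t)s * NGM + M_CP] = cp;
    out.global[(size_t)s * NGM + M_LP] = ps.lp;
    out.global[(size_t)s * NGM + M_EGLOB] = ps.eglobal;
    out.unreachable[s] = ps.unreachable_pairs;
    if (opt.do_local)
      out.global[(size_t)s * NGM + M_ELOC] = local_eff_nodes(g, nullptr);

    if (opt.do_norm) {
      double mcp, mlp;
      if (opt.reuse_denominators && fixed_mcp && fixed_mlp) {
        mcp = fixed_mcp[s]; mlp = fixed_mlp[s];
      } else {
        random_ensemble_means(g, ea, eb, have, opt.n_random, opt.swap_mult,
                              opt.attempt_mult, rng, mcp, mlp, opt.do_gamma);
      }
      out.mean_cp_rand[s] = mcp;
      out.mean_lp_rand[s] = mlp;
      double gamma = (R_finite(mcp) && mcp > 0.0) ? cp / mcp : NA_REAL;
      double lambda = (R_finite(mlp) && mlp > 0.0 && R_finite(ps.lp))
                          ? ps.lp / mlp : NA_REAL;
      out.global[(size_t)s * NGM + M_GAMMA] = gamma;
      out.global[(size_t)s * NGM + M_LAMBDA] = lambda;
      out.global[(size_t)s * NGM + M_SIGMA] =
          (R_finite(gamma) && R_finite(lambda) && lambda != 0.0)
              ? gamma / lambda : NA_REAL;
    }

    if (opt.do_nodal) {
      for (int i = 0; i < p; ++i) {
        out.nodal_eff[(size_t)s * p + i] = ne_buf[i];
        out.degree[(size_t)s * p + i] = g.deg(i);
      }
    }
    if (opt.do_betw) {
      betweenness_nodes(g, bc_buf);
      for (int i = 0; i < p; ++i) out.betw[(size_t)s * p + i] = bc_buf[i];
    }
  }
}

// AUC of a curve over the sparsity grid
static double curve_auc_c(const double* v, const double* x, int S,
                          bool trapezoid) {
  for (int i = 0; i < S; ++i) if (!R_finite(v[i])) return NA_REAL;
  if (S < 2) return NA_REAL;
  if (trapezoid) {
    double a = 0.0;
    for (int i = 1; i < S; ++i) a += 0.5 * (v[i] + v[i - 1]) * (x[i] - x[i - 1]);
    return a;
  }
  double step = (x[S - 1] - x[0]) / (S - 1);
  double sum = 0.0;
  for (int i = 0; i < S; ++i) sum += v[i];
  return sum * step;
}

static void global_aucs(const ChainOut& out, const double* spars, int S,
                        bool trapezoid, double* auc /*NGM*/) {
  std::vector<double> tmp(S);
  for (int m = 0; m < NGM; ++m) {
    for (int s = 0; s < S; ++s) tmp[s] = out.global[(size_t)s * NGM + m];
    auc[m] = curve_auc_c(tmp.data(), spars, S, trapezoid);
  }
}

static void nodal_aucs(const std::vector<double>& cur, int p,
                       const double* spars, int S, bool trapezoid,
                       double* auc /*p*/) {
  std::vector<double> tmp(S);
  for (int i = 0; i < p; ++i) {
    for (int s = 0; s < S; ++s) tmp[s] = cur[(size_t)s * p + i];
    auc[i] = curve_auc_c(tmp.data(), spars, S, trapezoid);
  }
}

// ---------------------------------------------------------------------------
// Exported single-graph metric functions
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_clustering(NumericMatrix adj) {
  BitGraph g = as_bitgraph(adj);
  NumericVector out(g.n);
  clustering_nodes(g, REAL(out));
  return out;
}

// [[Rcpp::export]]
List cpp_path_stats(NumericMatrix adj) {
  BitGraph g = as_bitgraph(adj);
  NumericVector ne(g.n);
  PathStats ps = path_stats(g, REAL(ne));
  return List::create(_["lp"] = ps.lp,
                      _["eglobal"] = ps.eglobal,
                      _["finite_pairs"] = (double)ps.finite_pairs,
                      _["unreachable_pairs"] = (double)ps.unreachable_pairs,
                      _["nodal_efficiency"] = ne);
}

// [[Rcpp::export]]
NumericVector cpp_local_efficiency(NumericMatrix adj) {
  BitGraph g = as_bitgraph(adj);
  NumericVector out(g.n);
  local_eff_nodes(g, REAL(out));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_betweenness(NumericMatrix adj) {
  BitGraph g = as_bitgraph(adj);
  NumericVector out(g.n);
  betweenness_nodes(g, REAL(out));
  return out;
}

// [[Rcpp::export]]
List cpp_rewire(NumericMatrix adj, double swap_mult, double attempt_mult) {
  BitGraph g = as_bitgraph(adj);
  Xoshiro rng; rng.seed_from_R();
  std::vector<int> ea, eb;
  for (int i = 0; i < g.n; ++i)
    for (int j = i + 1; j < g.n; ++j)
      if (g.has(i, j)) { ea.push_back(i); eb.push_back(j); }
  int E = (int)ea.size();
  long target = (long)(swap_mult * E + 0.5);
  long max_att = (long)(attempt_mult * (double)(target > 0 ? target : 1)) + 100;
  long done = rewire_graph(g, ea.data(), eb.data(), E, target, max_att, rng);
  NumericMatrix out(g.n, g.n);
  for (int i = 0; i < g.n; ++i)
    for (int j = 0; j < g.n; ++j)
      out(i, j) = g.has(i, j) ? 1.0 : 0.0;
  return List::create(_["adjacency"] = out,
                      _["target_swaps"] = (double)target,
                      _["achieved_swaps"] = (double)done);
}

// [[Rcpp::export]]
List cpp_normalized_metrics(NumericMatrix adj, int n_random, double swap_mult,
                            double attempt_mult) {
  BitGraph g = as_bitgraph(adj);
  Xoshiro rng; rng.seed_from_R();
  std::vector<int> ea, eb;
  for (int i = 0; i < g.n; ++i)
    for (int j = i + 1; j < g.n; ++j)
      if (g.has(i, j)) { ea.push_back(i); eb.push_back(j); }
  double cp = clustering_nodes(g, nullptr);
  PathStats ps = path_stats(g, nullptr);
  double mcp, mlp;
  random_ensemble_means(g, ea.data(), eb.data(), (int)ea.size(), n_random,
                        swap_mult, attempt_mult, rng, mcp, mlp);
  double gamma = (R_finite(mcp) && mcp > 0.0) ? cp / mcp : NA_REAL;
  double lambda = (R_finite(mlp) && mlp > 0.0 && R_finite(ps.lp))
                      ? ps.lp / mlp : NA_REAL;
  double sigma = (R_finite(gamma) && R_finite(lambda) && lambda != 0.0)
                     ? gamma / lambda : NA_REAL;
  return List::create(_["gamma"] = gamma, _["lambda"] = lambda,
                      _["sigma"] = sigma,
                      _["mean_cp_random"] = mcp, _["mean_lp_random"] = mlp,
                      _["cp"] = cp, _["lp"] = ps.lp);
}

// ---------------------------------------------------------------------------
// Exported chain: metric curves for one group of subjects
// ---------------------------------------------------------------------------

static NumericMatrix global_matrix(const ChainOut& out, int S) {
  NumericMatrix m(NGM, S);
  for (int s = 0; s < S; ++s)
    for (int g = 0; g < NGM; ++g)
      m(g, s) = out.global[(size_t)s * NGM + g];
  m.attr("dimnames") = List::create(
      CharacterVector::create("Cp", "Lp", "Eglobal", "Elocal", "Gamma",
                              "Lambda", "Sigma"),
      R_NilValue);
  return m;
}

static NumericMatrix nodal_matrix(const std::vector<double>& cur, int p, int S) {
  NumericMatrix m(p, S);
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < p; ++i) m(i, s) = cur[(size_t)s * p + i];
  return m;
}

// [[Rcpp::export]]
List cpp_group_curves(NumericMatrix vols, NumericVector sparsity, int n_random,
                      double swap_mult, double attempt_mult, bool do_norm,
                      bool do_gamma, bool do_local, bool do_betw,
                      bool do_nodal) {
  int n = vols.nrow(), p = vols.ncol();
  if (p > MAXN) stop("more than 64 nodes are not supported");
  if (n < 4) stop("at least 4 subjects are required per group");
  int S = sparsity.size();
  for (int s = 1; s < S; ++s)
    if (sparsity[s] <= sparsity[s - 1]) stop("sparsity grid must be increasing");
  Xoshiro rng; rng.seed_from_R();
  ChainOpts opt{n_random, swap_mult, attempt_mult, do_norm, do_gamma,
                do_local, do_betw, do_nodal, false};
  std::vector<double> zbuf((size_t)n * p);
  PairOrder po;
  ChainOut out;
  run_chain(REAL(vols), n, p, REAL(sparsity), S, opt, rng, zbuf, po, out);
  List res = List::create(
      _["global"] = global_matrix(out, S),
      _["requested_edges"] = IntegerVector(out.requested_k.begin(), out.requested_k.end()),
      _["achieved_edges"] = IntegerVector(out.achieved_k.begin(), out.achieved_k.end()),
      _["unreachable_pairs"] = NumericVector(out.unreachable.begin(), out.unreachable.end()),
      _["mean_cp_random"] = NumericVector(out.mean_cp_rand.begin(), out.mean_cp_rand.end()),
      _["mean_lp_random"] = NumericVector(out.mean_lp_rand.begin(), out.mean_lp_rand.end()),
      _["nodal_efficiency"] = do_nodal ? (SEXP)nodal_matrix(out.nodal_eff, p, S) : R_NilValue,
      _["degree"] = do_nodal ? (SEXP)nodal_matrix(out.degree, p, S) : R_NilValue,
      _["betweenness"] = do_betw ? (SEXP)nodal_matrix(out.betw, p, S) : R_NilValue);
  return res;
}

// ---------------------------------------------------------------------------
// Exported permutation engine
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_perm_test(NumericMatrix volsA, NumericMatrix volsB,
                   NumericVector sparsity, int n_perm, int n_random,
                   double swap_mult, double attempt_mult, bool do_norm,
                   bool do_gamma, bool do_local, bool do_betw, bool do_nodal,
                   bool trapezoid, bool reuse_ensembles) {
  int nA = volsA.nrow(), nB = volsB.nrow(), p = volsA.ncol();
  if (volsB.ncol() != p) stop("groups must share the node set");
  if (p > MAXN) stop("more than 64 nodes are not supported");
  if (nA < 4 || nB < 4) stop("at least 4 subjects are required per group");
  int S = sparsity.size();
  if (S < 2) stop("at least two sparsity values are required for AUC");
  for (int s = 1; s < S; ++s)
    if (sparsity[s] <= sparsity[s - 1]) stop("sparsity grid must be increasing");

  Xoshiro rng; rng.seed_from_R();
  ChainOpts opt{n_random, swap_mult, attempt_mult, do_norm, do_gamma,
                do_local, do_betw, do_nodal, false};
  int n = nA + nB;
  std::vector<double> pooled((size_t)n * p);
  // pooled column-major: group A rows first
  for (int j = 0; j < p; ++j) {
    double* col = pooled.data() + (size_t)j * n;
    for (int i = 0; i < nA; ++i) col[i] = volsA(i, j);
    for (int i = 0; i < nB; ++i) col[nA + i] = volsB(i, j);
  }
  std::vector<double> zbuf((size_t)std::max(nA, nB) * p);
  PairOrder po;
  ChainOut outA, outB;
  const double* spars = REAL(sparsity);

  // observed
  std::vector<double> XA((size_t)nA * p), XB((size_t)nB * p);
  for (int j = 0; j < p; ++j) {
    std::memcpy(XA.data() + (size_t)j * nA, pooled.data() + (size_t)j * n,
                sizeof(double) * nA);
    std::memcpy(XB.data() + (size_t)j * nB, pooled.data() + (size_t)j * n + nA,
                sizeof(double) * nB);
  }
  run_chain(XA.data(), nA, p, spars, S, opt, rng, zbuf, po, outA);
  run_chain(XB.data(), nB, p, spars, S, opt, rng, zbuf, po, outB);

  NumericVector aucA(NGM), aucB(NGM);
  global_aucs(outA, spars, S, trapezoid, REAL(aucA));
  global_aucs(outB, spars, S, trapezoid, REAL(aucB));
  CharacterVector mnames = CharacterVector::create(
      "Cp", "Lp", "Eglobal", "Elocal", "Gamma", "Lambda", "Sigma");
  aucA.attr("names") = mnames; aucB.attr("names") = mnames;

  NumericMatrix nodalA, nodalB, betwA, betwB;
  if (do_nodal) {
    nodalA = NumericMatrix(p, 2); nodalB = NumericMatrix(p, 2);
    nodal_aucs(outA.nodal_eff, p, spars, S, trapezoid, &nodalA(0, 0));
    nodal_aucs(outA.degree, p, spars, S, trapezoid, &nodalA(0, 1));
    nodal_aucs(outB.nodal_eff, p, spars, S, trapezoid, &nodalB(0, 0));
    nodal_aucs(outB.degree, p, spars, S, trapezoid, &nodalB(0, 1));
  }
  if (do_betw) {
    betwA = NumericMatrix(p, 1); betwB = NumericMatrix(p, 1);
    nodal_aucs(outA.betw, p, spars, S, trapezoid, &betwA(0, 0));
    nodal_aucs(outB.betw, p, spars, S, trapezoid, &betwB(0, 0));
  }

  // reuse option: freeze the observed groups' normalization denominators
  std::vector<double> fixA_cp, fixA_lp, fixB_cp, fixB_lp;
  if (reuse_ensembles && do_norm) {
    fixA_cp = outA.mean_cp_rand; fixA_lp = outA.mean_lp_rand;
    fixB_cp = outB.mean_cp_rand; fixB_lp = outB.mean_lp_rand;
    opt.reuse_denominators = true;
  }

  NumericMatrix null_global(n_perm, NGM);
  colnames(null_global) = mnames;
  NumericMatrix null_ne, null_deg, null_bc;
  if (do_nodal) { null_ne = NumericMatrix(n_perm, p); null_deg = NumericMatrix(n_perm, p); }
  if (do_betw) null_bc = NumericMatrix(n_perm, p);

  std::vector<int> idx(n);
  std::vector<double> YA((size_t)nA * p), YB((size_t)nB * p);
  double gA[NGM], gB[NGM];
  std::vector<double> nA_auc(p), nB_auc(p), dA_auc(p), dB_auc(p),
      bA_auc(p), bB_auc(p);

  for (int b = 0; b < n_perm; ++b) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)rng.below((uint32_t)(i + 1));
      std::swap(idx[i], idx[j]);
    }
    for (int j = 0; j < p; ++j) {
      const double* col = pooled.data() + (size_t)j * n;
      double* ya = YA.data() + (size_t)j * nA;
      double* yb = YB.data() + (size_t)j * nB;
      for (int i = 0; i < nA; ++i) ya[i] = col[idx[i]];
      for (int i = 0; i < nB; ++i) yb[i] = col[idx[nA + i]];
    }
    run_chain(YA.data(), nA, p, spars, S, opt, rng, zbuf, po, outA,
              fixA_cp.empty() ? nullptr : fixA_cp.data(),
              fixA_lp.empty() ? nullptr : fixA_lp.data());
    run_chain(YB.data(), nB, p, spars, S, opt, rng, zbuf, po, outB,
              fixB_cp.empty() ? nullptr : fixB_cp.data(),
              fixB_lp.empty() ? nullptr : fixB_lp.data());
    global_aucs(outA, spars, S, trapezoid, gA);
    global_aucs(outB, spars, S, trapezoid, gB);
    for (int m = 0; m < NGM; ++m) null_global(b, m) = gA[m] - gB[m];
    if (do_nodal) {
      nodal_aucs(outA.nodal_eff, p, spars, S, trapezoid, nA_auc.data());
      nodal_aucs(outB.nodal_eff, p, spars, S, trapezoid, nB_auc.data());
      nodal_aucs(outA.degree, p, spars, S, trapezoid, dA_auc.data());
      nodal_aucs(outB.degree, p, spars, S, trapezoid, dB_auc.data());
      for (int i = 0; i < p; ++i) {
        null_ne(b, i) = nA_auc[i] - nB_auc[i];
        null_deg(b, i) = dA_auc[i] - dB_auc[i];
      }
    }
    if (do_betw) {
      nodal_aucs(outA.betw, p, spars, S, trapezoid, bA_auc.data());
      nodal_aucs(outB.betw, p, spars, S, trapezoid, bB_auc.data());
      for (int i = 0; i < p; ++i) null_bc(b, i) = bA_auc[i] - bB_auc[i];
    }
    if ((b & 255) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["auc_A"] = aucA, _["auc_B"] = aucB,
      _["null_global"] = null_global,
      _["nodal_auc_A"] = do_nodal ? (SEXP)nodalA : R_NilValue,
      _["nodal_auc_B"] = do_nodal ? (SEXP)nodalB : R_NilValue,
      _["null_nodal_efficiency"] = do_nodal ? (SEXP)null_ne : R_NilValue,
      _["null_degree"] = do_nodal ? (SEXP)null_deg : R_NilValue,
      _["betweenness_auc_A"] = do_betw ? (SEXP)betwA : R_NilValue,
      _["betweenness_auc_B"] = do_betw ? (SEXP)betwB : R_NilValue,
      _["null_betweenness"] = do_betw ? (SEXP)null_bc : R_NilValue);
}
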