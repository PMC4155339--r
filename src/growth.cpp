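// Network growth engine: evaluates generator programs over sampled candidate
// arcs, maintains random-walk heuristic distances, and grows networks
// arc-by-arc. All randomness comes from R's RNG so runs are reproducible
// under set.seed().

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Prog {
  std::vector<int> kind;   // 0 operator, 1 variable, 2 constant
  std::vector<int> code;   // operator code 1..15 or variable code 1..7
  std::vector<int> arity;
  std::vector<double> value;
  bool need_d = false, need_dD = false, need_dR = false;
};

Prog unpack_prog(const List& p) {
  Prog out;
  out.kind  = as<std::vector<int>>(p["kind"]);
  out.code  = as<std::vector<int>>(p["code"]);
  out.arity = as<std::vector<int>>(p["arity"]);
  out.value = as<std::vector<double>>(p["value"]);
  for (size_t t = 0; t < out.kind.size(); ++t) {
    if (out.kind[t] == 1) {
      if (out.code[t] == 5) out.need_d = true;
      if (out.code[t] == 6) out.need_dD = true;
      if (out.code[t] == 7) out.need_dR = true;
    }
  }
  return out;
}

struct Ctx { double i, j, k, kp, d, dD, dR; };

inline double protect(double x) {
  if (std::isnan(x)) return 0.0;
  if (x > 1e300) return 1e300;
  if (x < -1e300) return -1e300;
  return x;
}

double eval_node(const Prog& p, int& pos, const Ctx& c) {
  const int idx = pos++;
  const int kind = p.kind[idx];
  if (kind == 2) return p.value[idx];
  if (kind == 1) {
    switch (p.code[idx]) {
      case 1: return c.i;
      case 2: return c.j;
      case 3: return c.k;
      case 4: return c.kp;
      case 5: return c.d;
      case 6: return c.dD;
      case 7: return c.dR;
    }
    return 0.0;
  }
  const int op = p.code[idx];
  const int ar = p.arity[idx];
  double a[4];
  for (int t = 0; t < ar; ++t) a[t] = eval_node(p, pos, c);
  double r = 0.0;
  switch (op) {
    case 1: r = a[0] + a[1]; break;
    case 2: r = a[0] - a[1]; break;
    case 3: r = a[0] * a[1]; break;
    case 4: r = (a[1] == 0.0) ? 0.0 : a[0] / a[1]; break;
    case 5: r = (a[0] == 0.0 && a[1] < 0.0) ? 0.0
                : std::pow(std::fabs(a[0]), a[1]); break;
    case 6: r = std::exp(a[0]); break;
    case 7: r = (a[0] <= 0.0) ? 0.0 : std::log(a[0]); break;
    case 8: r = std::fabs(a[0]); break;
    case 9: r = std::min(a[0], a[1]); break;
    case 10: r = std::max(a[0], a[1]); break;
    case 11: r = (a[0] > a[1]) ? a[2] : a[3]; break;
    case 12: r = (a[0] < a[1]) ? a[2] : a[3]; break;
    case 13: r = (a[0] == a[1]) ? a[2] : a[3]; break;
    case 14: r = (a[0] == 0.0) ? a[1] : a[2]; break;
    case 15: {
      long g = (long)std::trunc(a[0]);
      if (g < 1) g = 1;
      r = (((long)c.i) % g == ((long)c.j) % g) ? a[1] : a[2];
    } break;
  }
  return protect(r);
}

inline double eval_prog(const Prog& p, const Ctx& c) {
  int pos = 0;
  return eval_node(p, pos, c);
}

inline int runif_int(int n) {
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

// Bounded random-walk hop-count estimate from origin to target on the given
// adjacency view. W independent walks of at most L hops; the shortest hop at
// which any walk first hits the target, else the cap L+1.
int walk_distance(const std::vector<std::vector<int>>& adj,
                  int origin, int target, int W, int L) {
  int best = L + 1;
  for (int w = 0; w < W; ++w) {
    int cur = origin;
    for (int step = 1; step <= L && step < best; ++step) {
      const std::vector<int>& nb = adj[cur];
      if (nb.empty()) break;
      cur = nb[runif_int((int)nb.size())];
      if (cur == target) { best = step; break; }
    }
  }
  return best;
}

struct Growth {
  int n;
  bool directed;
  std::vector<std::vector<int>> adj_out, adj_in, adj_und;
  std::vector<int> deg_in, deg_out, deg_tot;
  std::unordered_set<long long> arcs;
  long long built = 0;

  Growth(int n_, bool directed_) : n(n_), directed(directed_) {
    adj_out.resize(n + 1);
    adj_in.resize(n + 1);
    adj_und.resize(n + 1);
    deg_in.assign(n + 1, 0);
    deg_out.assign(n + 1, 0);
    deg_tot.assign(n + 1, 0);
  }

  long long key(int a, int b) const {
    if (!directed && a > b) std::swap(a, b);
    return (long long)a * (n + 1) + b;
  }

  bool exists(int a, int b) const { return arcs.count(key(a, b)) > 0; }

  void add(int a, int b) {
    arcs.insert(key(a, b));
    ++built;
    if (directed) {
      adj_out[a].push_back(b);
      adj_in[b].push_back(a);
      ++deg_out[a]; ++deg_in[b];
    }
    adj_und[a].push_back(b);
    adj_und[b].push_back(a);
    ++deg_tot[a]; ++deg_tot[b];
  }

  long long total_legal() const {
    long long nn = n;
    return directed ? nn * (nn - 1) : nn * (nn - 1) / 2;
  }
};

// One growth run. progB, when non-null, shadows progA: at every step both
// probability vectors over the shared candidate sample are compared and the
// mean absolute difference is accumulated into *dsum / *dcount.
IntegerMatrix grow_impl(const Prog& A, const Prog* B, int n, int m,
                        bool directed, double s_r, int min_sample,
                        int W, int L, double* dsum, long long* dcount) {
  Growth g(n, directed);
  IntegerMatrix edges(m, 2);
  const bool need_d  = A.need_d  || (B && B->need_d);
  const bool need_dD = directed && (A.need_dD || (B && B->need_dD));
  const bool need_dR = directed && (A.need_dR || (B && B->need_dR));

  long long want = (long long)std::llround(s_r * (double)n * (double)n);
  if (want < min_sample) want = min_sample;

  std::vector<int> ci, cj;
  std::vector<double> wA, wB;
  std::unordered_set<long long> seen;

  for (int step = 0; step < m; ++step) {
    long long remaining = g.total_legal() - g.built;
    if (remaining <= 0) stop("network complete: no legal candidate arcs left");
    int s = (int)std::min<long long>(want, remaining);

    ci.clear(); cj.clear(); seen.clear();
    while ((int)ci.size() < s) {
      int a = runif_int(n) + 1;
      int b = runif_int(n) + 1;
      if (a == b) continue;
      long long kk = g.key(a, b);
      if (g.arcs.count(kk) || seen.count(kk)) continue;
      seen.insert(kk);
      ci.push_back(a);
      cj.push_back(b);
    }

    wA.assign(s, 0.0);
    if (B) wB.assign(s, 0.0);
    for (int c = 0; c < s; ++c) {
      Ctx ctx;
      ctx.i = ci[c];
      ctx.j = cj[c];
      if (directed) { ctx.k = g.deg_out[ci[c]]; ctx.kp = g.deg_in[cj[c]]; }
      else          { ctx.k = g.deg_tot[ci[c]]; ctx.kp = g.deg_tot[cj[c]]; }
      ctx.d  = need_d  ? walk_distance(g.adj_und, ci[c], cj[c], W, L) : 0.0;
      ctx.dD = need_dD ? walk_distance(g.adj_out, ci[c], cj[c], W, L) : 0.0;
      ctx.dR = need_dR ? walk_distance(g.adj_in,  ci[c], cj[c], W, L) : 0.0;
      wA[c] = eval_prog(A, ctx);
      if (B) wB[c] = eval_prog(*B, ctx);
    }

    // P_ij proportional to pi(w) * w; all-nonpositive sample falls back to
    // the uniform distribution.
    double totA = 0.0;
    for (int c = 0; c < s; ++c) if (wA[c] > 0.0) totA += wA[c];
    bool uniA = (totA <= 0.0);
    if (uniA) totA = s;

    if (B) {
      double totB = 0.0;
      for (int c = 0; c < s; ++c) if (wB[c] > 0.0) totB += wB[c];
      bool uniB = (totB <= 0.0);
      if (uniB) totB = s;
      for (int c = 0; c < s; ++c) {
        double pA = uniA ? 1.0 / s : (wA[c] > 0.0 ? wA[c] / totA : 0.0);
        double pB = uniB ? 1.0 / s : (wB[c] > 0.0 ? wB[c] / totB : 0.0);
        *dsum += std::fabs(pA - pB);
        ++(*dcount);
      }
    }

    double u = unif_rand() * totA;
    int chosen = s - 1;
    double acc = 0.0;
    for (int c = 0; c < s; ++c) {
      acc += uniA ? 1.0 : (wA[c] > 0.0 ? wA[c] : 0.0);
      if (u <= acc) { chosen = c; break; }
    }

    g.add(ci[chosen], cj[chosen]);
    edges(step, 0) = ci[chosen];
    edges(step, 1) = cj[chosen];
  }
  return edges;
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix grow_network_cpp(List prog, int n, int m, bool directed,
                               double s_r, int min_sample, int W, int L) {
  Prog A = unpack_prog(prog);
  return grow_impl(A, nullptr, n, m, directed, s_r, min_sample, W, L,
                   nullptr, nullptr);
}

// [[Rcpp::export]]
double generator_distance_cpp(List prog_w, List prog_wp, int n, int m,
                              bool directed, double s_r, int min_sample,
                              int W, int L) {
  Prog A = unpack_prog(prog_w);
  Prog B = unpack_prog(prog_wp);
  double dsum = 0.0;
  long long dcount = 0;
  grow_impl(A, &B, n, m, directed, s_r, min_sample, W, L, &dsum, &dcount);
  return dcount > 0 ? dsum / (double)dcount : 0.0;
}

// [[Rcpp::export]]
IntegerVector walk_distances_cpp(IntegerMatrix edges, int n, bool directed,
                                 int origin, int target, int W, int L) {
  std::vector<std::vector<int>> adj_out(n + 1), adj_in(n + 1), adj_und(n + 1);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    if (directed) { adj_out[a].push_back(b); adj_in[b].push_back(a); }
    adj_und[a].push_back(b);
    adj_und[b].push_back(a);
  }
  int d = walk_distance(adj_und, origin, target, W, L);
  if (!directed) return IntegerVector::create(d, NA_INTEGER, NA_INTEGER);
  int dD = walk_distance(adj_out, origin, target, W, L);
  int dR = walk_distance(adj_in, origin, target, W, L);
  return IntegerVector::create(d, dD, dR);
}
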