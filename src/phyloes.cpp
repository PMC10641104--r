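#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <utility>
#include <vector>

using namespace Rcpp;

// Unrooted binary leaf-labelled trees on nodes 1..2n-2: leaves 1..n,
// internal nodes n+1..2n-2, 2n-3 edges. Edges are kept as (min,max) pairs;
// "canonical order" is ascending by (min endpoint, max endpoint), the same
// order the step-wise encoding uses.

typedef std::pair<int, int> Edge;
typedef std::vector<Edge> EdgeVec;

namespace {

struct Adj {
  int n;  // taxa
  int N;  // nodes = 2n - 2
  std::vector<int> deg;
  std::vector<std::array<int, 3> > nb;

  void build(const EdgeVec &e, int n_) {
    n = n_;
    N = 2 * n - 2;
    deg.assign(N + 1, 0);
    nb.assign(N + 1, std::array<int, 3>());
    for (EdgeVec::const_iterator it = e.begin(); it != e.end(); ++it) {
      int u = it->first, v = it->second;
      if (u < 1 || u > N || v < 1 || v > N) stop("node label out of range");
      if (u == v) stop("self-loop edge");
      if (deg[u] >= 3 || deg[v] >= 3) stop("node of degree > 3: not binary");
      nb[u][deg[u]++] = v;
      nb[v][deg[v]++] = u;
    }
  }
};

void bfs(const Adj &a, int src, std::vector<int> &dist, std::vector<int> &q) {
  std::fill(dist.begin(), dist.end(), -1);
  int head = 0, tail = 0;
  dist[src] = 0;
  q[tail++] = src;
  while (head < tail) {
    int u = q[head++];
    for (int k = 0; k < a.deg[u]; ++k) {
      int v = a.nb[u][k];
      if (dist[v] < 0) {
        dist[v] = dist[u] + 1;
        q[tail++] = v;
      }
    }
  }
}

// Balanced length L = sum over unordered pairs {i,j} of d_ij * 2^(1-tau_ij),
// accumulated in fixed row-major pair order for run-to-run bit stability.
double balanced_length(const EdgeVec &e, int n, const NumericMatrix &d) {
  Adj a;
  a.build(e, n);
  std::vector<int> dist(a.N + 1), q(a.N + 1);
  double L = 0.0;
  for (int i = 1; i <= n; ++i) {
    bfs(a, i, dist, q);
    for (int j = i + 1; j <= n; ++j) {
      if (dist[j] < 0) stop("tree is not connected");
      L += std::ldexp(d(i - 1, j - 1), 1 - dist[j]);
    }
  }
  return L;
}

EdgeVec from_matrix(const IntegerMatrix &E) {
  EdgeVec e(E.nrow());
  for (int i = 0; i < E.nrow(); ++i) {
    int u = E(i, 0), v = E(i, 1);
    e[i] = Edge(std::min(u, v), std::max(u, v));
  }
  return e;
}

IntegerMatrix to_matrix(const EdgeVec &e) {
  IntegerMatrix E(e.size(), 2);
  for (size_t i = 0; i < e.size(); ++i) {
    E(i, 0) = e[i].first;
    E(i, 1) = e[i].second;
  }
  return E;
}

void canon(EdgeVec &e) { std::sort(e.begin(), e.end()); }

void replace_edge(EdgeVec &e, int u, int v, int x, int y) {
  Edge target(std::min(u, v), std::max(u, v));
  for (EdgeVec::iterator it = e.begin(); it != e.end(); ++it)
    if (*it == target) {
      *it = Edge(std::min(x, y), std::max(x, y));
      return;
    }
  stop("internal error: edge (%d,%d) not found", u, v);
}

// Best strictly improving NNI neighbour; edges scanned in canonical order,
// within an edge the A<->C swap before the A<->D swap (A = smaller-label
// subtree at one endpoint). First of equal improvements wins (strict <).
bool nni_best(const EdgeVec &base, int n, const NumericMatrix &d, double cur,
              EdgeVec &out, double &best) {
  EdgeVec e = base;
  canon(e);
  Adj a;
  a.build(e, n);
  best = cur;
  bool found = false;
  for (size_t k = 0; k < e.size(); ++k) {
    int u = e[k].first, v = e[k].second;
    if (u <= n || v <= n) continue;  // internal edges only
    int A[2], C[2];
    int ia = 0, ic = 0;
    for (int t = 0; t < 3; ++t)
      if (a.nb[u][t] != v) A[ia++] = a.nb[u][t];
    for (int t = 0; t < 3; ++t)
      if (a.nb[v][t] != u) C[ic++] = a.nb[v][t];
    std::sort(A, A + 2);
    std::sort(C, C + 2);
    for (int w = 0; w < 2; ++w) {
      EdgeVec cand = e;
      replace_edge(cand, u, A[0], u, C[w]);
      replace_edge(cand, v, C[w], v, A[0]);
      double L = balanced_length(cand, n, d);
      if (L < best) {
        best = L;
        out = cand;
        found = true;
      }
    }
  }
  return found;
}

// Best strictly improving SPR neighbour. For each edge (canonical order) and
// each pruning direction (smaller endpoint's subtree first), the pruned
// subtree is regrafted onto every edge outside it and not incident to the
// attachment node, in canonical order.
bool spr_best(const EdgeVec &base, int n, const NumericMatrix &d, double cur,
              EdgeVec &out, double &best) {
  EdgeVec e = base;
  canon(e);
  Adj a;
  a.build(e, n);
  int N = 2 * n - 2;
  std::vector<char> mark(N + 1);
  std::vector<int> stk(N + 1);
  best = cur;
  bool found = false;
  for (size_t k = 0; k < e.size(); ++k) {
    int ends[2];
    ends[0] = e[k].first;
    ends[1] = e[k].second;
    for (int dir = 0; dir < 2; ++dir) {
      int s = ends[dir], p = ends[1 - dir];
      if (a.deg[p] != 3) continue;  // attachment node must be internal
      std::fill(mark.begin(), mark.end(), 0);
      int top = 0;
      stk[top++] = s;
      mark[s] = 1;
      while (top) {
        int x = stk[--top];
        for (int t = 0; t < a.deg[x]; ++t) {
          int y = a.nb[x][t];
          if (y != p && !mark[y]) {
            mark[y] = 1;
            stk[top++] = y;
          }
        }
      }
      int xx = 0, yy = 0;
      for (int t = 0; t < 3; ++t) {
        int y = a.nb[p][t];
        if (y != s) {
          if (!xx)
            xx = y;
          else
            yy = y;
        }
      }
      for (size_t j = 0; j < e.size(); ++j) {
        int u = e[j].first, v = e[j].second;
        if (mark[u] || mark[v] || u == p || v == p) continue;
        EdgeVec cand = e;
        replace_edge(cand, p, xx, xx, yy);
        replace_edge(cand, p, yy, p, u);
        replace_edge(cand, u, v, p, v);
        double L = balanced_length(cand, n, d);
        if (L < best) {
          best = L;
          out = cand;
          found = true;
        }
      }
    }
  }
  return found;
}

List descend(const IntegerMatrix &E, const NumericMatrix &d, bool use_spr) {
  int n = d.nrow();
  EdgeVec e = from_matrix(E);
  canon(e);
  double cur = balanced_length(e, n, d);
  std::vector<double> trace;
  int iters = 0;
  for (;;) {
    EdgeVec nxt;
    double best;
    bool ok = use_spr ? spr_best(e, n, d, cur, nxt, best)
                      : nni_best(e, n, d, cur, nxt, best);
    if (!ok) break;
    e = nxt;
    canon(e);
    cur = best;
    ++iters;
    trace.push_back(cur);
    if (iters > 1000000) stop("descent failed to terminate");
  }
  return List::create(_["edges"] = to_matrix(e), _["length"] = cur,
                      _["iterations"] = iters, _["trace"] = wrap(trace));
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_path_lengths(IntegerMatrix E, int n) {
  EdgeVec e = from_matrix(E);
  Adj a;
  a.build(e, n);
  std::vector<int> dist(a.N + 1), q(a.N + 1);
  IntegerMatrix tau(n, n);
  for (int i = 1; i <= n; ++i) {
    bfs(a, i, dist, q);
    for (int j = 1; j <= n; ++j) {
      if (dist[j] < 0) stop("tree is not connected");
      tau(i - 1, j - 1) = dist[j];
    }
  }
  return tau;
}

// [[Rcpp::export]]
double cpp_bme_length(IntegerMatrix E, NumericMatrix d) {
  EdgeVec e = from_matrix(E);
  return balanced_length(e, d.nrow(), d);
}

// [[Rcpp::export]]
List cpp_bnni(IntegerMatrix E, NumericMatrix d) { return descend(E, d, false); }

// [[Rcpp::export]]
List cpp_bspr(IntegerMatrix E, NumericMatrix d) { return descend(E, d, true); }
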