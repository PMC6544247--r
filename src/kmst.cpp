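#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

// Kruskal k-MST machinery. Trees are built sequentially: tree t is an MST of
// the complete graph minus all edges used by trees 1..t-1. Edges are
// examined in (weight, smaller index, larger index) order; WITHIN a group of
// equal-weight edges, edges touching low-degree nodes are preferred (degree
// sum first) and remaining ties are ordered by a random key drawn from R's
// RNG. Any maximal acceptable subset of an equal-weight group gives the
// same tree weight (matroid exchange), so this only picks the topology.
// The degree priority keeps degrees small where ties are massive (e.g.
// boundary atoms of clipped data), which the chi-squared limit's
// no-large-hub condition requires; the random key keeps the graph
// independent of the input sample order, which the permutation null
// requires (labels usually arrive grouped, and any index-based tie rule
// would preferentially join same-group samples). No randomness is consumed
// when edge weights are distinct, and a fixed seed gives a fixed graph.

struct Edge {
  double w;
  int a, b;  // 0-based original node indices, a < b
};

static inline bool edge_less(const Edge& x, const Edge& y) {
  if (x.w != y.w) return x.w < y.w;
  if (x.a != y.a) return x.a < y.a;
  return x.b < y.b;
}

struct UnionFind {
  std::vector<int> parent;
  void init(int n) {
    parent.resize(n);
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  bool unite(int x, int y) {
    int rx = find(x), ry = find(y);
    if (rx == ry) return false;
    parent[rx] = ry;
    return true;
  }
};

// Lazy edge supplier: the dense path pre-fills the buffer; the 1-D path
// appends equal-weight runs on demand. extend() returns false on exhaustion.
struct EdgeSource {
  virtual bool extend(std::vector<Edge>& buf) = 0;
  virtual ~EdgeSource() {}
};

struct RunItem {
  int degsum;
  double rkey;
  int a, b, idx;
};
struct RunItemGreater {
  bool operator()(const RunItem& x, const RunItem& y) const {
    if (x.degsum != y.degsum) return x.degsum > y.degsum;
    if (x.rkey != y.rkey) return x.rkey > y.rkey;
    if (x.a != y.a) return x.a > y.a;
    return x.b > y.b;
  }
};

// Sequential Kruskal over a (lazily grown) globally sorted edge buffer;
// returns indices of selected edges. `deg` accumulates union-graph degrees
// across trees; equal-weight runs are processed through a lazy min-heap on
// (current degree sum, a, b).
static std::vector<int> kruskal_seq(std::vector<Edge>& buf, EdgeSource* src,
                                    int n, int k) {
  std::vector<int> sel;
  sel.reserve((size_t)k * (n - 1));
  std::vector<char> used;
  used.resize(buf.size(), 0);
  std::vector<int> deg(n, 0);
  UnionFind uf;
  for (int t = 0; t < k; ++t) {
    uf.init(n);
    int found = 0;
    size_t pos = 0;
    while (found < n - 1) {
      if (pos >= buf.size()) {
        if (src == 0 || !src->extend(buf))
          stop("could not complete spanning tree %d of %d", t + 1, k);
        used.resize(buf.size(), 0);
      }
      double w = buf[pos].w;
      size_t run_end = pos + 1;
      while (run_end < buf.size() && buf[run_end].w == w) ++run_end;
      if (run_end - pos == 1) {
        const Edge& e = buf[pos];
        if (!used[pos] && uf.unite(e.a, e.b)) {
          used[pos] = 1;
          sel.push_back((int)pos);
          ++deg[e.a];
          ++deg[e.b];
          ++found;
        }
        pos = run_end;
        continue;
      }
      std::priority_queue<RunItem, std::vector<RunItem>, RunItemGreater> heap;
      for (size_t i = pos; i < run_end; ++i)
        if (!used[i])
          heap.push({deg[buf[i].a] + deg[buf[i].b], unif_rand(), buf[i].a,
                     buf[i].b, (int)i});
      while (!heap.empty() && found < n - 1) {
        RunItem it = heap.top();
        heap.pop();
        int cur = deg[it.a] + deg[it.b];
        if (cur != it.degsum) {  // stale key: re-queue with updated degrees
          it.degsum = cur;
          heap.push(it);
          continue;
        }
        if (uf.unite(it.a, it.b)) {
          used[it.idx] = 1;
          sel.push_back(it.idx);
          ++deg[it.a];
          ++deg[it.b];
          ++found;
        }
      }
      pos = run_end;
    }
  }
  return sel;
}

// [[Rcpp::export(name = ".cpp_kmst_dense")]]
IntegerMatrix cpp_kmst_dense(NumericMatrix d, int k) {
  int n = d.nrow();
  std::vector<Edge> edges;
  edges.reserve((size_t)n * (n - 1) / 2);
  for (int a = 0; a < n - 1; ++a)
    for (int b = a + 1; b < n; ++b) edges.push_back({d(a, b), a, b});
  std::sort(edges.begin(), edges.end(), edge_less);
  std::vector<int> sel = kruskal_seq(edges, 0, n, k);
  IntegerMatrix out(sel.size(), 2);
  for (size_t i = 0; i < sel.size(); ++i) {
    out(i, 0) = edges[sel[i]].a + 1;
    out(i, 1) = edges[sel[i]].b + 1;
  }
  return out;
}

// ---- 1-D fast path --------------------------------------------------------
//
// For a single feature the candidate edges are gaps between sorted values.
// Edges are streamed in globally sorted (w, a, b) order from a min-heap over
// "span" successors: for sorted positions i < j the weight s[j] - s[i] is
// increasing in j, so each left endpoint contributes edges in sorted order
// and a heap of one pending edge per left endpoint merges the streams.
// Equal-weight edges are drained into a batch and sorted by (a, b) so tie
// order matches the dense sort exactly.

struct HeapEdge {
  double w;
  int a, b;  // original indices, a < b
  int i, j;  // sorted positions, i < j
};
struct HeapEdgeGreater {
  bool operator()(const HeapEdge& x, const HeapEdge& y) const {
    if (x.w != y.w) return x.w > y.w;
    if (x.a != y.a) return x.a > y.a;
    return x.b > y.b;
  }
};

class Edge1DStream : public EdgeSource {
  const std::vector<double>& s;
  const std::vector<int>& ord;
  int n;
  std::priority_queue<HeapEdge, std::vector<HeapEdge>, HeapEdgeGreater> heap;

  HeapEdge make(int i, int j) const {
    int a = ord[i], b = ord[j];
    if (a > b) std::swap(a, b);
    return {s[j] - s[i], a, b, i, j};
  }

 public:
  Edge1DStream(const std::vector<double>& s_, const std::vector<int>& ord_)
      : s(s_), ord(ord_), n((int)s_.size()) {
    for (int i = 0; i + 1 < n; ++i) heap.push(make(i, i + 1));
  }
  // Append the next complete equal-weight run of globally-sorted edges.
  bool extend(std::vector<Edge>& buf) {
    if (heap.empty()) return false;
    size_t start = buf.size();
    HeapEdge e = heap.top();
    heap.pop();
    double w = e.w;
    buf.push_back({e.w, e.a, e.b});
    if (e.j + 1 < n) heap.push(make(e.i, e.j + 1));
    while (!heap.empty() && heap.top().w == w) {
      HeapEdge f = heap.top();
      heap.pop();
      buf.push_back({f.w, f.a, f.b});
      if (f.j + 1 < n) heap.push(make(f.i, f.j + 1));
    }
    std::sort(buf.begin() + start, buf.end(), edge_less);
    return true;
  }
};

// k-MST of a single 1-D feature; returns selected edges in Kruskal order.
static std::vector<Edge> kmst_1d(const std::vector<double>& x, int k) {
  int n = (int)x.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return a < b;
  });
  std::vector<double> s(n);
  for (int i = 0; i < n; ++i) s[i] = x[ord[i]];

  Edge1DStream stream(s, ord);
  std::vector<Edge> buf;
  std::vector<int> idx = kruskal_seq(buf, &stream, n, k);
  std::vector<Edge> sel;
  sel.reserve(idx.size());
  for (int i : idx) sel.push_back(buf[i]);
  return sel;
}

// [[Rcpp::export(name = ".cpp_kmst_1d")]]
IntegerMatrix cpp_kmst_1d(NumericVector x, int k) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<Edge> sel = kmst_1d(xv, k);
  IntegerMatrix out(sel.size(), 2);
  for (size_t i = 0; i < sel.size(); ++i) {
    out(i, 0) = sel[i].a + 1;
    out(i, 1) = sel[i].b + 1;
  }
  return out;
}

// Per-feature 3-MST screening engine: for each column of X build the k-MST,
// count within-group edges R_j, and return R (p x J) plus the graph pair
// count C = 0.5 * sum(deg^2) - |G| each column's graph yields.
// [[Rcpp::export(name = ".cpp_kmst_screen_1d")]]
List cpp_kmst_screen_1d(NumericMatrix X, IntegerVector y, int J, int k) {
  int n = X.nrow(), p = X.ncol();
  IntegerMatrix R(p, J);
  NumericVector C(p);
  std::vector<double> xv(n);
  std::vector<int> deg(n);
  for (int col = 0; col < p; ++col) {
    for (int i = 0; i < n; ++i) xv[i] = X(i, col);
    std::vector<Edge> sel = kmst_1d(xv, k);
    std::fill(deg.begin(), deg.end(), 0);
    for (const Edge& e : sel) {
      ++deg[e.a];
      ++deg[e.b];
      int ya = y[e.a], yb = y[e.b];
      if (ya == yb) ++R(col, ya - 1);
    }
    double ss = 0;
    for (int i = 0; i < n; ++i) ss += (double)deg[i] * deg[i];
    C[col] = 0.5 * ss - (double)sel.size();
  }
  return List::create(_["R"] = R, _["C"] = C,
                      _["n_edges"] = (double)k * (n - 1));
}

// [[Rcpp::export(name = ".cpp_count_R")]]
IntegerVector cpp_count_R(IntegerMatrix edges, IntegerVector y, int J) {
  IntegerVector R(J);
  for (int i = 0; i < edges.nrow(); ++i) {
    int ya = y[edges(i, 0) - 1], yb = y[edges(i, 1) - 1];
    if (ya == yb) ++R[ya - 1];
  }
  return R;
}

// B label permutations (uniform, via R's RNG so set.seed() governs);
// returns the B x J matrix of within-group edge counts.
// [[Rcpp::export(name = ".cpp_perm_R")]]
IntegerMatrix cpp_perm_R(IntegerMatrix edges, IntegerVector y, int J, int B) {
  int n = y.size(), m = edges.nrow();
  IntegerMatrix out(B, J);
  std::vector<int> perm(y.begin(), y.end());
  for (int b = 0; b < B; ++b) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;  // guard against unif_rand() == 1
      std::swap(perm[i], perm[j]);
    }
    for (int e = 0; e < m; ++e) {
      int ya = perm[edges(e, 0) - 1], yb = perm[edges(e, 1) - 1];
      if (ya == yb) ++out(b, ya - 1);
    }
  }
  return out;
}

// sum over edges e of |A_e| * |B_e|, where A_e is e plus edges sharing a
// node with e, and B_e is A_e plus edges sharing a node with any member of
// A_e (i.e. edges touching {u, v} or a neighbour of u or v).
// [[Rcpp::export(name = ".cpp_sum_AeBe")]]
double cpp_sum_AeBe(IntegerMatrix edges, int n) {
  int m = edges.nrow();
  std::vector<std::vector<int>> adj(n);
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    adj[a].push_back(b);
    adj[b].push_back(a);
    ++deg[a];
    ++deg[b];
  }
  std::vector<char> mark(n, 0);
  std::vector<int> touched;
  double total = 0;
  for (int e = 0; e < m; ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    double Ae = deg[u] + deg[v] - 1;
    touched.clear();
    mark[u] = 1;
    touched.push_back(u);
    mark[v] = 1;
    touched.push_back(v);
    for (int w : adj[u])
      if (!mark[w]) {
        mark[w] = 1;
        touched.push_back(w);
      }
    for (int w : adj[v])
      if (!mark[w]) {
        mark[w] = 1;
        touched.push_back(w);
      }
    int Be = 0;
    for (int f = 0; f < m; ++f)
      if (mark[edges(f, 0) - 1] || mark[edges(f, 1) - 1]) ++Be;
    total += Ae * (double)Be;
    for (int w : touched) mark[w] = 0;
  }
  return total;
}
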