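// Left-right planarity test (Brandes' formulation of de Fraysseix-Rosenstiehl)
// and the greedy planarity-constrained filter (PMFG) built on top of it.
//
// Vertices are 0-based ints; edges are undirected, simple, no self-loops.
// The test runs in O(n + m); the PMFG pass re-tests each candidate edge,
// which is fast enough for the vocabulary sizes seen in fluency data
// (a few hundred words at most).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Interval {
  int low, high; // directed-edge ids, -1 = empty
  Interval() : low(-1), high(-1) {}
  bool empty() const { return low == -1 && high == -1; }
};

struct ConflictPair {
  Interval L, R;
  bool empty() const { return L.empty() && R.empty(); }
};

class LRPlanarity {
public:
  // edges: m x 2 (0-based). Assumes simple graph, no loops.
  LRPlanarity(int n, const std::vector<std::pair<int, int> > &edges)
      : n_(n), m_((int)edges.size()) {
    src_.resize(2 * m_);
    dst_.resize(2 * m_);
    twin_.resize(2 * m_);
    adj_.assign(n_, std::vector<int>());
    for (int i = 0; i < m_; ++i) {
      int u = edges[i].first, v = edges[i].second;
      src_[2 * i] = u; dst_[2 * i] = v;
      src_[2 * i + 1] = v; dst_[2 * i + 1] = u;
      twin_[2 * i] = 2 * i + 1; twin_[2 * i + 1] = 2 * i;
      adj_[u].push_back(2 * i);
      adj_[v].push_back(2 * i + 1);
    }
  }

  bool is_planar() {
    if (n_ <= 4 || m_ <= 8) return true; // K5 needs 10 edges, K3,3 needs 9
    if (m_ > 3 * n_ - 6) return false;   // Euler bound

    height_.assign(n_, -1);
    parent_edge_.assign(n_, -1);
    oriented_.assign(2 * m_, false);
    lowpt_.assign(2 * m_, 0);
    lowpt2_.assign(2 * m_, 0);
    nesting_.assign(2 * m_, 0);
    ref_.assign(2 * m_, -1);
    lowpt_edge_.assign(2 * m_, -1);
    stack_bottom_.assign(2 * m_, 0);

    for (int v = 0; v < n_; ++v) {
      if (height_[v] == -1) {
        height_[v] = 0;
        dfs_orient(v);
      }
    }

    // ordered adjacency: outgoing oriented edges sorted by nesting depth
    ordered_adj_.assign(n_, std::vector<int>());
    for (int v = 0; v < n_; ++v) {
      for (size_t k = 0; k < adj_[v].size(); ++k) {
        int e = adj_[v][k];
        if (oriented_[e]) ordered_adj_[v].push_back(e);
      }
      std::sort(ordered_adj_[v].begin(), ordered_adj_[v].end(),
                [this](int a, int b) { return nesting_[a] < nesting_[b]; });
    }

    S_.clear();
    for (int v = 0; v < n_; ++v) {
      if (parent_edge_[v] == -1) {
        if (!dfs_test(v)) return false;
      }
    }
    return true;
  }

private:
  int n_, m_;
  std::vector<int> src_, dst_, twin_;
  std::vector<std::vector<int> > adj_, ordered_adj_;
  std::vector<int> height_, parent_edge_;
  std::vector<char> oriented_;
  std::vector<int> lowpt_, lowpt2_, nesting_, ref_, lowpt_edge_, stack_bottom_;
  std::vector<ConflictPair> S_;

  // phase 1: DFS orientation computing lowpoints and nesting depth
  void dfs_orient(int root) {
    std::vector<size_t> stack_k;
    std::vector<int> stack_v;
    stack_v.push_back(root);
    stack_k.push_back(0);
    while (!stack_v.empty()) {
      int v = stack_v.back();
      size_t &k = stack_k.back();
      bool descended = false;
      while (k < adj_[v].size()) {
        int e = adj_[v][k];
        ++k;
        if (oriented_[e] || oriented_[twin_[e]]) continue;
        oriented_[e] = true;
        int w = dst_[e];
        lowpt_[e] = height_[v];
        lowpt2_[e] = height_[v];
        if (height_[w] == -1) { // tree edge
          parent_edge_[w] = e;
          height_[w] = height_[v] + 1;
          stack_v.push_back(w);
          stack_k.push_back(0);
          descended = true;
          break;
        } else { // back edge
          lowpt_[e] = height_[w];
          finish_edge(v, e);
        }
      }
      if (descended) continue;
      if (k >= adj_[v].size()) {
        stack_v.pop_back();
        stack_k.pop_back();
        int e = parent_edge_[v];
        if (e != -1) finish_edge(src_[e], e);
      }
    }
  }

  // nesting depth of e and lowpoint update of e's parent edge
  void finish_edge(int v, int e) {
    nesting_[e] = 2 * lowpt_[e];
    if (lowpt2_[e] < height_[v]) nesting_[e] += 1; // chordal
    int pe = parent_edge_[v];
    if (pe != -1) {
      if (lowpt_[e] < lowpt_[pe]) {
        lowpt2_[pe] = std::min(lowpt_[pe], lowpt2_[e]);
        lowpt_[pe] = lowpt_[e];
      } else if (lowpt_[e] > lowpt_[pe]) {
        lowpt2_[pe] = std::min(lowpt2_[pe], lowpt_[e]);
      } else {
        lowpt2_[pe] = std::min(lowpt2_[pe], lowpt2_[e]);
      }
    }
  }

  int lowest(const ConflictPair &P) const {
    if (P.L.empty()) return lowpt_[P.R.low];
    if (P.R.empty()) return lowpt_[P.L.low];
    return std::min(lowpt_[P.L.low], lowpt_[P.R.low]);
  }

  bool conflicting(const Interval &I, int b) const {
    return !I.empty() && lowpt_[I.high] > lowpt_[b];
  }

  // phase 2: testing DFS (recursive; depth bounded by n)
  bool dfs_test(int v) {
    int e = parent_edge_[v];
    const std::vector<int> &out = ordered_adj_[v];
    for (size_t i = 0; i < out.size(); ++i) {
      int ei = out[i];
      stack_bottom_[ei] = (int)S_.size();
      int w = dst_[ei];
      if (ei == parent_edge_[w]) { // tree edge
        if (!dfs_test(w)) return false;
      } else { // back edge
        lowpt_edge_[ei] = ei;
        ConflictPair P;
        P.R.low = ei;
        P.R.high = ei;
        S_.push_back(P);
      }
      if (lowpt_[ei] < height_[v]) { // ei has a return edge
        if (i == 0) {
          lowpt_edge_[e] = lowpt_edge_[ei];
        } else if (!add_constraints(ei, e)) {
          return false;
        }
      }
    }
    if (e != -1) remove_back_edges(e);
    return true;
  }

  bool add_constraints(int ei, int e) {
    ConflictPair P;
    // merge return edges of ei into P.R
    while (true) {
      ConflictPair Q = S_.back();
      S_.pop_back();
      if (!Q.L.empty()) std::swap(Q.L, Q.R);
      if (!Q.L.empty()) return false; // not planar
      if (lowpt_[Q.R.low] > lowpt_[e]) { // merge intervals
        if (P.R.empty()) P.R.high = Q.R.high;
        else ref_[P.R.low] = Q.R.high;
        P.R.low = Q.R.low;
      } else { // align
        ref_[Q.R.low] = lowpt_edge_[e];
      }
      if ((int)S_.size() == stack_bottom_[ei]) break;
    }
    // merge conflicting return edges of e_1 .. e_{i-1} into P.L
    while (!S_.empty() &&
           (conflicting(S_.back().L, ei) || conflicting(S_.back().R, ei))) {
      ConflictPair Q = S_.back();
      S_.pop_back();
      if (conflicting(Q.R, ei)) std::swap(Q.L, Q.R);
      if (conflicting(Q.R, ei)) return false; // not planar
      // merge interval below lowpt(ei) into P.R
      if (P.R.low != -1) ref_[P.R.low] = Q.R.high;
      else P.R.high = Q.R.high;
      if (Q.R.low != -1) P.R.low = Q.R.low;
      if (P.L.empty()) P.L.high = Q.L.high;
      else ref_[P.L.low] = Q.L.high;
      P.L.low = Q.L.low;
    }
    if (!P.empty()) S_.push_back(P);
    return true;
  }

  void remove_back_edges(int e) {
    int u = src_[e];
    // drop entire conflict pairs returning to u
    while (!S_.empty() && lowest(S_.back()) == height_[u]) S_.pop_back();
    if (!S_.empty()) {
      ConflictPair P = S_.back();
      S_.pop_back();
      // trim left interval
      while (P.L.high != -1 && dst_[P.L.high] == u) P.L.high = ref_[P.L.high];
      if (P.L.high == -1 && P.L.low != -1) {
        ref_[P.L.low] = P.R.low;
        P.L.low = -1;
      }
      // trim right interval
      while (P.R.high != -1 && dst_[P.R.high] == u) P.R.high = ref_[P.R.high];
      if (P.R.high == -1 && P.R.low != -1) {
        ref_[P.R.low] = P.L.low;
        P.R.low = -1;
      }
      S_.push_back(P);
    }
    // side of e is the side of a highest return edge
    if (lowpt_[e] < height_[u] && !S_.empty()) {
      int hl = S_.back().L.high, hr = S_.back().R.high;
      if (hl != -1 && (hr == -1 || lowpt_[hl] > lowpt_[hr])) ref_[e] = hl;
      else ref_[e] = hr;
    }
  }
};

bool planar_edge_vec(int n, const std::vector<std::pair<int, int> > &edges) {
  LRPlanarity lr(n, edges);
  return lr.is_planar();
}

} // namespace

// [[Rcpp::export(name = ".lr_is_planar")]]
bool lr_is_planar(int n, IntegerMatrix edges) {
  std::vector<std::pair<int, int> > ev;
  ev.reserve(edges.nrow());
  for (int i = 0; i < edges.nrow(); ++i) {
    int u = edges(i, 0), v = edges(i, 1);
    if (u == v) stop("self-loops are not allowed");
    if (u < 0 || v < 0 || u >= n || v >= n) stop("edge endpoint out of range");
    ev.push_back(std::make_pair(u, v));
  }
  return planar_edge_vec(n, ev);
}

// Greedy PMFG edge selection. W: full symmetric weight matrix (diagonal
// ignored). Candidate edges are ranked by weight, descending; ties broken by
// (i, j) index order, which equals lexicographic word order when the matrix
// follows a sorted vocabulary. Returns the selected edges as a k x 2 matrix
// of 0-based indices; stops once 3(n-2) edges are placed.
// [[Rcpp::export(name = ".pmfg_edges")]]
IntegerMatrix pmfg_edges(NumericMatrix W) {
  int n = W.nrow();
  if (n != W.ncol()) stop("weight matrix must be square");
  if (n < 3) stop("PMFG requires at least 3 nodes");

  struct Cand { double w; int i, j; };
  std::vector<Cand> cands;
  cands.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double w = W(i, j);
      if (!R_finite(w)) stop("non-finite weight encountered");
      Cand c; c.w = w; c.i = i; c.j = j;
      cands.push_back(c);
    }
  }
  std::stable_sort(cands.begin(), cands.end(), [](const Cand &a, const Cand &b) {
    if (a.w != b.w) return a.w > b.w;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });

  int target = 3 * (n - 2);
  std::vector<std::pair<int, int> > kept;
  kept.reserve(target);
  for (size_t k = 0; k < cands.size() && (int)kept.size() < target; ++k) {
    kept.push_back(std::make_pair(cands[k].i, cands[k].j));
    // graphs with <= 8 edges are always planar (K5 has 10, K3,3 has 9)
    if (kept.size() > 8 && !planar_edge_vec(n, kept)) kept.pop_back();
  }

  IntegerMatrix out((int)kept.size(), 2);
  for (size_t k = 0; k < kept.size(); ++k) {
    out((int)k, 0) = kept[k].first;
    out((int)k, 1) = kept[k].second;
  }
  return out;
}
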