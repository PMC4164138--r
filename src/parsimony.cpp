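#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Trees are passed as a 1-based parent vector (parent[i-1] == 0 marks the
// root) plus a tiprow vector mapping tip nodes to rows of the state matrix
// (0 for internal nodes).  States are small non-negative integers (0..31).

static void build_traversal(const IntegerVector& parent,
                            std::vector<int>& post,
                            std::vector<std::vector<int> >& kids,
                            int& root) {
  int m = parent.size();
  kids.assign(m + 1, std::vector<int>());
  root = 0;
  for (int i = 1; i <= m; ++i) {
    int p = parent[i - 1];
    if (p == 0) {
      if (root != 0) stop("tree has more than one root");
      root = i;
    } else if (p < 0 || p > m) {
      stop("parent index out of range");
    } else {
      kids[p].push_back(i);
    }
  }
  if (root == 0) stop("tree has no root");
  post.clear();
  post.reserve(m);
  std::vector<std::pair<int, int> > stk;
  stk.push_back(std::make_pair(root, 0));
  while (!stk.empty()) {
    std::pair<int, int>& top = stk.back();
    if (top.second < (int)kids[top.first].size()) {
      int c = kids[top.first][top.second++];
      stk.push_back(std::make_pair(c, 0));
    } else {
      post.push_back(top.first);
      stk.pop_back();
    }
  }
  if ((int)post.size() != m) stop("tree is not connected");
}

// Wagner (ordered-state) length via Farris interval passes; binary trees only.
// [[Rcpp::export]]
double wagner_length_cpp(IntegerVector parent, IntegerVector tiprow,
                         IntegerMatrix states) {
  int m = parent.size(), C = states.ncol(), root;
  std::vector<int> post;
  std::vector<std::vector<int> > kids;
  build_traversal(parent, post, kids, root);
  std::vector<int> lo((m + 1) * C), hi((m + 1) * C);
  double total = 0.0;
  for (size_t k = 0; k < post.size(); ++k) {
    int v = post[k];
    int* lv = &lo[(size_t)v * C];
    int* hv = &hi[(size_t)v * C];
    const std::vector<int>& ch = kids[v];
    if (ch.empty()) {
      int row = tiprow[v - 1];
      if (row < 1 || row > states.nrow()) stop("tip without a state row");
      for (int c = 0; c < C; ++c) lv[c] = hv[c] = states(row - 1, c);
    } else {
      if (ch.size() != 2) stop("wagner scorer requires a binary tree");
      int* l1 = &lo[(size_t)ch[0] * C];
      int* h1 = &hi[(size_t)ch[0] * C];
      int* l2 = &lo[(size_t)ch[1] * C];
      int* h2 = &hi[(size_t)ch[1] * C];
      for (int c = 0; c < C; ++c) {
        int L = l1[c] > l2[c] ? l1[c] : l2[c];
        int H = h1[c] < h2[c] ? h1[c] : h2[c];
        if (L > H) {          // disjoint intervals: pay the gap
          total += L - H;
          lv[c] = H; hv[c] = L;
        } else {
          lv[c] = L; hv[c] = H;
        }
      }
    }
  }
  return total;
}

// Fitch (unordered-state) length via bitmask intersections; binary trees only.
// [[Rcpp::export]]
double fitch_length_cpp(IntegerVector parent, IntegerVector tiprow,
                        IntegerMatrix states) {
  int m = parent.size(), C = states.ncol(), root;
  std::vector<int> post;
  std::vector<std::vector<int> > kids;
  build_traversal(parent, post, kids, root);
  std::vector<unsigned int> msk((size_t)(m + 1) * C);
  double total = 0.0;
  for (size_t k = 0; k < post.size(); ++k) {
    int v = post[k];
    unsigned int* mv = &msk[(size_t)v * C];
    const std::vector<int>& ch = kids[v];
    if (ch.empty()) {
      int row = tiprow[v - 1];
      if (row < 1 || row > states.nrow()) stop("tip without a state row");
      for (int c = 0; c < C; ++c) {
        int s = states(row - 1, c);
        if (s < 0 || s > 31) stop("state outside [0,31]");
        mv[c] = 1u << s;
      }
    } else {
      if (ch.size() != 2) stop("fitch scorer requires a binary tree");
      unsigned int* a = &msk[(size_t)ch[0] * C];
      unsigned int* b = &msk[(size_t)ch[1] * C];
      for (int c = 0; c < C; ++c) {
        unsigned int inter = a[c] & b[c];
        if (inter == 0u) { total += 1.0; mv[c] = a[c] | b[c]; }
        else mv[c] = inter;
      }
    }
  }
  return total;
}

// Sankoff generalized parsimony: per-character minimum total cost under an
// arbitrary state-to-state cost matrix.  Handles multifurcations.
// [[Rcpp::export]]
NumericVector sankoff_length_cpp(IntegerVector parent, IntegerVector tiprow,
                                 IntegerMatrix states, NumericMatrix cost) {
  int m = parent.size(), C = states.ncol(), root;
  int S = cost.nrow();
  if (cost.ncol() != S) stop("cost matrix must be square");
  std::vector<int> post;
  std::vector<std::vector<int> > kids;
  build_traversal(parent, post, kids, root);
  const double INF = 1e300;
  NumericVector out(C);
  std::vector<double> dp((size_t)(m + 1) * S);
  for (int c = 0; c < C; ++c) {
    for (size_t k = 0; k < post.size(); ++k) {
      int v = post[k];
      double* dv = &dp[(size_t)v * S];
      const std::vector<int>& ch = kids[v];
      if (ch.empty()) {
        int row = tiprow[v - 1];
        if (row < 1 || row > states.nrow()) stop("tip without a state row");
        int s = states(row - 1, c);
        if (s < 0 || s >= S) stop("state outside cost matrix range");
        for (int i = 0; i < S; ++i) dv[i] = (i == s) ? 0.0 : INF;
      } else {
        for (int i = 0; i < S; ++i) dv[i] = 0.0;
        for (size_t q = 0; q < ch.size(); ++q) {
          double* dc = &dp[(size_t)ch[q] * S];
          for (int i = 0; i < S; ++i) {
            double best = INF;
            for (int j = 0; j < S; ++j) {
              double w = cost(i, j) + dc[j];
              if (w < best) best = w;
            }
            dv[i] += best;
          }
        }
      }
    }
    double best = INF;
    double* dr = &dp[(size_t)root * S];
    for (int i = 0; i < S; ++i) if (dr[i] < best) best = dr[i];
    out[c] = best;
  }
  return out;
}
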