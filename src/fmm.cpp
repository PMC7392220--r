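#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// First-order upwind fast marching solver for |grad T| = 1/F on a
// 4-neighbour grid with unit spacing.  Each point is accepted exactly once,
// in (time, row, col) order so runs are bit-reproducible even under ties.

struct Node {
  double t;
  int r, c;
};

struct NodeCmp {
  bool operator()(const Node& a, const Node& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.r != b.r) return a.r > b.r;
    return a.c > b.c;
  }
};

// W: strictly positive speed values; seeds: 0-based (row, col) pairs;
// domain: TRUE where the front may propagate.  Returns raw arrival times,
// +Inf where unreached (outside the domain or disconnected from the seeds).
// [[Rcpp::export]]
NumericMatrix fmm_arrival_c(NumericMatrix W, IntegerMatrix seeds,
                            LogicalMatrix domain) {
  const int nr = W.nrow(), nc = W.ncol();
  NumericMatrix T(nr, nc);
  std::fill(T.begin(), T.end(), R_PosInf);
  // state: 0 = far, 1 = trial (narrow band), 2 = accepted
  IntegerMatrix state(nr, nc);

  std::priority_queue<Node, std::vector<Node>, NodeCmp> heap;
  for (int s = 0; s < seeds.nrow(); ++s) {
    int r = seeds(s, 0), c = seeds(s, 1);
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("seed outside image bounds");
    T(r, c) = 0.0;
    state(r, c) = 1;
    heap.push({0.0, r, c});
  }

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};

  while (!heap.empty()) {
    Node nd = heap.top();
    heap.pop();
    if (state(nd.r, nd.c) == 2) continue;      // lazily deleted duplicate
    if (nd.t > T(nd.r, nd.c)) continue;        // stale entry
    state(nd.r, nd.c) = 2;

    for (int k = 0; k < 4; ++k) {
      int r = nd.r + dr[k], c = nd.c + dc[k];
      if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
      if (!domain(r, c) || state(r, c) == 2) continue;

      // smallest accepted neighbour value per axis
      double a = R_PosInf, b = R_PosInf;
      if (r > 0      && state(r - 1, c) == 2) a = T(r - 1, c);
      if (r < nr - 1 && state(r + 1, c) == 2) a = std::min(a, T(r + 1, c));
      if (c > 0      && state(r, c - 1) == 2) b = T(r, c - 1);
      if (c < nc - 1 && state(r, c + 1) == 2) b = std::min(b, T(r, c + 1));
      if (!R_FINITE(a) && !R_FINITE(b)) continue;

      double f = 1.0 / W(r, c);
      double lo = std::min(a, b), hi = std::max(a, b), t;
      if (hi - lo >= f) {
        t = lo + f;                            // one-sided update
      } else {
        double d = a - b;
        t = 0.5 * (a + b + std::sqrt(2.0 * f * f - d * d));
      }
      if (t < T(r, c)) {
        T(r, c) = t;
        state(r, c) = 1;
        heap.push({t, r, c});
      }
    }
  }
  return T;
}

// 8-connected labelling of a logical mask, labels assigned in raster order.
// [[Rcpp::export]]
IntegerMatrix label8_c(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            if (di == 0 && dj == 0) continue;
            int r = p.first + di, c = p.second + dj;
            if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
            if (mask(r, c) && lab(r, c) == 0) {
              lab(r, c) = next;
              stack.push_back(std::make_pair(r, c));
            }
          }
        }
      }
    }
  }
  return lab;
}
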