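#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Nearest point on a densely sampled parametric curve, for every node of a
// rectangular grid. Two-stage search: a coarse scan over every `stride`-th
// curve sample, then an exhaustive scan of the window around the coarse
// minimum (wrapping for closed curves). Accuracy is set by the curve
// sampling density, which the caller controls.

// [[Rcpp::export]]
List cpp_nearest_curve(NumericVector gx, NumericVector gy, NumericVector px,
                       NumericVector py, bool closed) {
  const int nx = gx.size(), ny = gy.size(), m = px.size();
  int stride = (int)std::sqrt((double)m);
  if (stride < 1) stride = 1;
  NumericMatrix dist(nx, ny);
  IntegerMatrix idx(nx, ny);
  for (int i = 0; i < nx; ++i) {
    const double x = gx[i];
    for (int j = 0; j < ny; ++j) {
      const double y = gy[j];
      double best = R_PosInf;
      int bi = 0;
      for (int t = 0; t < m; t += stride) {
        double dx = px[t] - x, dy = py[t] - y;
        double d2 = dx * dx + dy * dy;
        if (d2 < best) { best = d2; bi = t; }
      }
      int lo = bi - stride, hi = bi + stride;
      for (int t = lo; t <= hi; ++t) {
        int tt = t;
        if (closed) {
          tt = ((t % m) + m) % m;
        } else if (t < 0 || t >= m) {
          continue;
        }
        double dx = px[tt] - x, dy = py[tt] - y;
        double d2 = dx * dx + dy * dy;
        if (d2 < best) { best = d2; bi = tt; }
      }
      dist(i, j) = std::sqrt(best);
      idx(i, j) = bi + 1; // 1-based for R
    }
  }
  return List::create(_["dist"] = dist, _["index"] = idx);
}

// Simulate a finite-state Markov chain given row-wise cumulative transition
// probabilities; returns 1-based visited state indices.

// [[Rcpp::export]]
IntegerVector cpp_chain_sim(NumericMatrix cum, int n_steps, int init) {
  const int m = cum.nrow();
  IntegerVector out(n_steps);
  int cur = init - 1;
  if (cur < 0 || cur >= m) stop("invalid initial state");
  for (int t = 0; t < n_steps; ++t) {
    double u = unif_rand();
    int lo = 0, hi = m - 1;
    while (lo < hi) { // first index with cum >= u
      int mid = (lo + hi) / 2;
      if (cum(cur, mid) >= u) hi = mid; else lo = mid + 1;
    }
    cur = lo;
    out[t] = cur + 1;
  }
  return out;
}
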