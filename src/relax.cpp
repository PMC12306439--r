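#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Iterative pairwise disk de-overlap. Each sweep moves every overlapping
// pair apart along its centre line by step_frac * overlap depth, split
// equally, which preserves the (unweighted) colony centroid. Coincident
// centres get a deterministic golden-angle direction so stacks of daughters
// fan out reproducibly. Returns final positions plus a per-cell overlap
// fraction (sum of residual pair overlap depths over the cell's diameter),
// the crowding proxy fed back into growth.
// [[Rcpp::export]]
List relax_overlaps_cpp(NumericVector x, NumericVector y, NumericVector r,
                        int iterations, double step_frac) {
  int n = x.size();
  NumericVector px = clone(x), py = clone(y);
  const double golden = 2.39996322972865332; // radians

  for (int it = 0; it < iterations; ++it) {
    bool moved = false;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = px[j] - px[i];
        double dy = py[j] - py[i];
        double d2 = dx * dx + dy * dy;
        double rsum = r[i] + r[j];
        if (d2 >= rsum * rsum) continue;
        double d = std::sqrt(d2);
        double ux, uy;
        if (d < 1e-12) {
          double ang = golden * (double)(i + 1) + 0.5 * golden * (double)(j + 1);
          ux = std::cos(ang); uy = std::sin(ang);
          d = 0.0;
        } else {
          ux = dx / d; uy = dy / d;
        }
        double push = 0.5 * step_frac * (rsum - d);
        px[i] -= push * ux; py[i] -= push * uy;
        px[j] += push * ux; py[j] += push * uy;
        moved = true;
      }
    }
    if (!moved) break;
  }

  NumericVector overlap(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = px[j] - px[i];
      double dy = py[j] - py[i];
      double rsum = r[i] + r[j];
      double d2 = dx * dx + dy * dy;
      if (d2 >= rsum * rsum) continue;
      double depth = rsum - std::sqrt(d2);
      overlap[i] += depth / (2.0 * r[i]);
      overlap[j] += depth / (2.0 * r[j]);
    }
  }
  return List::create(_["x"] = px, _["y"] = py, _["overlap"] = overlap);
}
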