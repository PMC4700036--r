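#include <Rcpp.h>
using namespace Rcpp;

// Empty-circumcircle scan: a triangle (i,j,k) is Delaunay iff no other point
// lies strictly inside its circumcircle; its three edges are Delaunay edges.
// O(n^3) triples with early exit on the inner test; adequate for the section
// sizes this package targets (a few hundred bundles) and exact enough once
// co-circular quadruples are broken by the caller's deterministic jitter.
//
// Returns the symmetric adjacency matrix plus a flag set when some empty
// circumcircle carries a fourth point on its boundary (within tolerance) —
// the degenerate case the caller resolves by perturbing and re-running.
// [[Rcpp::export(name = ".delaunay_scan")]]
List delaunay_scan(NumericMatrix pts) {
  const int n = pts.nrow();
  NumericVector x = pts(_, 0), y = pts(_, 1);

  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  const double span = std::max(xmax - xmin, ymax - ymin);
  const double area_eps = 1e-12 * span * span;   // collinear-triple cutoff

  LogicalMatrix adj(n, n);
  bool degenerate = false;

  for (int i = 0; i < n - 2; ++i) {
    for (int j = i + 1; j < n - 1; ++j) {
      const double abx = x[j] - x[i], aby = y[j] - y[i];
      for (int k = j + 1; k < n; ++k) {
        const double acx = x[k] - x[i], acy = y[k] - y[i];
        const double d = 2.0 * (abx * acy - aby * acx);
        if (std::fabs(d) < area_eps) continue;   // collinear: no circumcircle

        const double ab2 = abx * abx + aby * aby;
        const double ac2 = acx * acx + acy * acy;
        const double ux = (acy * ab2 - aby * ac2) / d;   // centre rel. to i
        const double uy = (abx * ac2 - acx * ab2) / d;
        const double r2 = ux * ux + uy * uy;
        const double cx = x[i] + ux, cy = y[i] + uy;
        const double tol = 1e-9 * r2;

        bool empty = true, on_circle = false;
        for (int m = 0; m < n; ++m) {
          if (m == i || m == j || m == k) continue;
          const double dx = x[m] - cx, dy = y[m] - cy;
          const double d2 = dx * dx + dy * dy;
          if (d2 < r2 - tol) { empty = false; break; }
          if (d2 <= r2 + tol) on_circle = true;
        }
        if (empty) {
          if (on_circle) degenerate = true;
          adj(i, j) = adj(j, i) = true;
          adj(j, k) = adj(k, j) = true;
          adj(i, k) = adj(k, i) = true;
        }
      }
    }
  }
  return List::create(_["adj"] = adj, _["degenerate"] = degenerate);
}
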