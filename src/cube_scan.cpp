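#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Evaluate the population SD of point-to-candidate distances on a cubic
// lattice of candidate centers: center + (i,j,k)*step for i,j,k in
// [-half_n, half_n], visited in lexicographic (i,j,k) order. Returns the
// winning offset under the tie-break: smallest SD, then smallest squared
// displacement from the current center, then first in lexicographic order.
//
// [[Rcpp::export]]
List cube_scan_cpp(NumericMatrix pts, NumericVector center,
                   double step, int half_n) {
  const int n = pts.nrow();
  const double cx = center[0], cy = center[1], cz = center[2];
  const double *x = &pts(0, 0), *y = &pts(0, 1), *z = &pts(0, 2);

  double best_sd = R_PosInf, best_mean = 0.0;
  int bi = 0, bj = 0, bk = 0;
  long best_disp2 = 0;
  bool have = false;

  for (int i = -half_n; i <= half_n; ++i) {
    const double ox = cx + i * step;
    for (int j = -half_n; j <= half_n; ++j) {
      const double oy = cy + j * step;
      for (int k = -half_n; k <= half_n; ++k) {
        const double oz = cz + k * step;
        double s = 0.0, s2 = 0.0;
        for (int p = 0; p < n; ++p) {
          const double dx = x[p] - ox, dy = y[p] - oy, dz = z[p] - oz;
          const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          s += d;
          s2 += d * d;
        }
        const double mean = s / n;
        double var = s2 / n - mean * mean;
        if (var < 0.0) var = 0.0;
        const double sd = std::sqrt(var);
        const long disp2 = (long)i * i + (long)j * j + (long)k * k;
        bool better = false;
        if (!have || sd < best_sd) better = true;
        else if (sd == best_sd && disp2 < best_disp2) better = true;
        if (better) {
          have = true;
          best_sd = sd;
          best_mean = mean;
          best_disp2 = disp2;
          bi = i; bj = j; bk = k;
        }
      }
    }
  }
  return List::create(_["offset"] = IntegerVector::create(bi, bj, bk),
                      _["sd"] = best_sd, _["mean"] = best_mean);
}

// Population mean and SD of point-to-center distances.
//
// [[Rcpp::export]]
NumericVector radial_stats_cpp(NumericMatrix pts, NumericVector center) {
  const int n = pts.nrow();
  const double cx = center[0], cy = center[1], cz = center[2];
  double s = 0.0, s2 = 0.0;
  for (int p = 0; p < n; ++p) {
    const double dx = pts(p, 0) - cx, dy = pts(p, 1) - cy,
                 dz = pts(p, 2) - cz;
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    s += d;
    s2 += d * d;
  }
  const double mean = s / n;
  double var = s2 / n - mean * mean;
  if (var < 0.0) var = 0.0;
  return NumericVector::create(mean, std::sqrt(var));
}
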