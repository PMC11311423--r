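#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Minimum Euclidean distance from each row of `a` to the rows of `b`.
// Both are n x 3 world-mm coordinate matrices. Plain quadratic scan with a
// running-minimum squared distance; sizes here (surfel sets of a few
// thousand points) keep this well inside interactive budgets.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  if (nb == 0) stop("empty reference point set");
  NumericVector out(na);
  const double *ax = &a(0, 0), *ay = na ? &a(0, 1) : ax, *az = na ? &a(0, 2) : ax;
  const double *bx = &b(0, 0), *by = &b(0, 1), *bz = &b(0, 2);
  for (int i = 0; i < na; ++i) {
    const double xi = ax[i], yi = ay[i], zi = az[i];
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - bx[j], dy = yi - by[j], dz = zi - bz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        if (best == 0.0) break;
      }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Overall minimum distance between two point sets, with early exit once a
// zero is found. Used for OAR-to-PTV surface distances.
// [[Rcpp::export]]
double cpp_min_dist_between(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  if (na == 0 || nb == 0) stop("empty point set");
  const double *ax = &a(0, 0), *ay = &a(0, 1), *az = &a(0, 2);
  const double *bx = &b(0, 0), *by = &b(0, 1), *bz = &b(0, 2);
  double best = R_PosInf;
  for (int i = 0; i < na; ++i) {
    const double xi = ax[i], yi = ay[i], zi = az[i];
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - bx[j], dy = yi - by[j], dz = zi - bz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        if (best == 0.0) return 0.0;
      }
    }
  }
  return std::sqrt(best);
}
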