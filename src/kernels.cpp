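#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Trajectories arrive time x dim (column-major); copy to a contiguous
// point-major layout once so pairwise work stays cache-friendly.
static std::vector<double> transpose_points(const NumericMatrix &X) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> P((size_t)n * d);
  for (int k = 0; k < d; ++k)
    for (int i = 0; i < n; ++i)
      P[(size_t)i * d + k] = X(i, k);
  return P;
}

static inline double sqdist(const double *a, const double *b, int d) {
  double s = 0.0;
  for (int k = 0; k < d; ++k) {
    double t = a[k] - b[k];
    s += t * t;
  }
  return s;
}

// Percentile (type-7 quantile, linear interpolation) of all pairwise
// Euclidean distances between rows of X. Distances are materialised once
// (n(n-1)/2 doubles) and selected with nth_element, never fully sorted.
// [[Rcpp::export]]
double cpp_pairwise_quantile(NumericMatrix X, double prob) {
  const R_xlen_t n = X.nrow();
  const int d = X.ncol();
  if (n < 2) stop("need at least 2 points");
  std::vector<double> P = transpose_points(X);
  const R_xlen_t m = n * (n - 1) / 2;
  std::vector<double> dist;
  dist.reserve(m);
  for (R_xlen_t i = 0; i < n - 1; ++i) {
    const double *pi = &P[(size_t)i * d];
    for (R_xlen_t j = i + 1; j < n; ++j)
      dist.push_back(std::sqrt(sqdist(pi, &P[(size_t)j * d], d)));
  }
  double h = (m - 1) * prob;
  R_xlen_t lo = (R_xlen_t)std::floor(h);
  R_xlen_t hi = lo + 1 < m ? lo + 1 : lo;
  std::nth_element(dist.begin(), dist.begin() + lo, dist.end());
  double dlo = dist[lo];
  std::nth_element(dist.begin() + lo, dist.begin() + hi, dist.end());
  double dhi = dist[hi];
  return dlo + (h - lo) * (dhi - dlo);
}

// Forward recurrence scan. For each scanned index i (0-based, in
// [scan_from, scan_to]), skip the contiguous run of points after i that stay
// within theta of P(i), then find the first later point (up to the last row)
// that re-enters the theta-ball. Returns the delay in steps, or NA.
// With min_steps > 0, re-entries closer than min_steps to the anchor are
// treated as quasi-periodic noise excursions: their within-theta run is
// skipped and the search continues, so the delay of a recurrent point is
// always >= min_steps.
// [[Rcpp::export]]
IntegerVector cpp_recurrence_scan(NumericMatrix X, double theta,
                                  int scan_from, int scan_to,
                                  int min_steps = 0) {
  const int n = X.nrow();
  const int d = X.ncol();
  const double th2 = theta * theta;
  if (scan_from < 0 || scan_to >= n || scan_from > scan_to)
    stop("scan indices out of range");
  std::vector<double> P = transpose_points(X);
  IntegerVector out(scan_to - scan_from + 1, NA_INTEGER);
  for (int i = scan_from; i <= scan_to; ++i) {
    const double *pi = &P[(size_t)i * d];
    int j = i + 1;
    while (j < n && sqdist(pi, &P[(size_t)j * d], d) < th2) ++j;
    while (j < n) {
      while (j < n && sqdist(pi, &P[(size_t)j * d], d) >= th2) ++j;
      if (j >= n) break;
      if (j - i >= min_steps) {
        out[i - scan_from] = j - i;
        break;
      }
      while (j < n && sqdist(pi, &P[(size_t)j * d], d) < th2) ++j;
    }
  }
  return out;
}

// Contiguous run of trajectory rows around `anchor` (0-based) staying within
// `radius` of it; returns 0-based {lo, hi} inclusive.
// [[Rcpp::export]]
IntegerVector cpp_neighbourhood_run(NumericMatrix X, int anchor,
                                    double radius) {
  const int n = X.nrow();
  const int d = X.ncol();
  if (anchor < 0 || anchor >= n) stop("anchor out of range");
  const double r2 = radius * radius;
  std::vector<double> P = transpose_points(X);
  const double *pa = &P[(size_t)anchor * d];
  int lo = anchor;
  while (lo > 0 && sqdist(pa, &P[(size_t)(lo - 1) * d], d) < r2) --lo;
  int hi = anchor;
  while (hi < n - 1 && sqdist(pa, &P[(size_t)(hi + 1) * d], d) < r2) ++hi;
  return IntegerVector::create(lo, hi);
}

static double directed_hausdorff(const std::vector<double> &A, int na,
                                 const std::vector<double> &B, int nb,
                                 int d) {
  double hmax = 0.0;
  for (int i = 0; i < na; ++i) {
    const double *ai = &A[(size_t)i * d];
    double mn = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double s = sqdist(ai, &B[(size_t)j * d], d);
      if (s < mn) {
        mn = s;
        if (mn <= hmax) break;  // cannot raise the running maximum
      }
    }
    if (mn > hmax) hmax = mn;
  }
  return std::sqrt(hmax);
}

// Symmetric Hausdorff distance max{h(A->B), h(B->A)} with h the maximum
// over one set of the minimum Euclidean distance to the other.
// [[Rcpp::export]]
double cpp_hausdorff(NumericMatrix A, NumericMatrix B) {
  if (A.ncol() != B.ncol()) stop("dimension mismatch");
  std::vector<double> PA = transpose_points(A), PB = transpose_points(B);
  double hab = directed_hausdorff(PA, A.nrow(), PB, B.nrow(), A.ncol());
  double hba = directed_hausdorff(PB, B.nrow(), PA, A.nrow(), A.ncol());
  return hab > hba ? hab : hba;
}

// [[Rcpp::export]]
double cpp_directed_hausdorff(NumericMatrix A, NumericMatrix B) {
  if (A.ncol() != B.ncol()) stop("dimension mismatch");
  std::vector<double> PA = transpose_points(A), PB = transpose_points(B);
  return directed_hausdorff(PA, A.nrow(), PB, B.nrow(), A.ncol());
}
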