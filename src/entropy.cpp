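#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Chebyshev-distance template counting shared by approximate and sample
// entropy. phi_m = count fraction of template pairs within tolerance r.

// Approximate entropy: self-matches included, Phi_m(r) - Phi_{m+1}(r),
// C_i^m(r) counted over all j (including j == i), log is natural.
// [[Rcpp::export]]
double apen_c(NumericVector x, int m, double r) {
  int N = x.size();
  if (N <= m + 1) stop("apen: series too short for embedding dimension");
  double phi[2];
  for (int dim = m; dim <= m + 1; ++dim) {
    int M = N - dim + 1;
    double acc = 0.0;
    for (int i = 0; i < M; ++i) {
      int cnt = 0;
      for (int j = 0; j < M; ++j) {
        double d = 0.0;
        for (int k = 0; k < dim; ++k) {
          double a = std::fabs(x[i + k] - x[j + k]);
          if (a > d) d = a;
          if (d > r) break;
        }
        if (d <= r) ++cnt;
      }
      acc += std::log((double)cnt / (double)M);
    }
    phi[dim - m] = acc / (double)M;
  }
  return phi[0] - phi[1];
}

// Sample entropy: self-matches excluded, SampEn = ln C_m - ln C_{m+1}
// with C_dim the total count of matching template pairs (i != j).
// Returns NA if no matches at dimension m+1 (undefined / infinite).
// [[Rcpp::export]]
double sampen_c(NumericVector x, int m, double r) {
  int N = x.size();
  if (N <= m + 1) stop("sampen: series too short for embedding dimension");
  long long cnt[2] = {0, 0};
  for (int dim = m; dim <= m + 1; ++dim) {
    int M = N - dim + 1;
    long long c = 0;
    for (int i = 0; i < M; ++i) {
      for (int j = i + 1; j < M; ++j) {
        double d = 0.0;
        for (int k = 0; k < dim; ++k) {
          double a = std::fabs(x[i + k] - x[j + k]);
          if (a > d) d = a;
          if (d > r) break;
        }
        if (d <= r) ++c;
      }
    }
    cnt[dim - m] = c;
  }
  if (cnt[0] == 0 || cnt[1] == 0) return NA_REAL;
  return std::log((double)cnt[0]) - std::log((double)cnt[1]);
}

// Higuchi normalized curve lengths L(k) for k = 1..k_max: for each start
// m, L_m(k) = [ sum_i |X(m+ik) - X(m+(i-1)k)| * (N-1) / (floor((N-m)/k) k) ] / k,
// averaged over m = 1..k.
// [[Rcpp::export]]
NumericVector higuchi_lengths_c(NumericVector x, int k_max) {
  int N = x.size();
  NumericVector L(k_max);
  for (int k = 1; k <= k_max; ++k) {
    double acc = 0.0;
    for (int m = 1; m <= k; ++m) {
      int nk = (N - m) / k;  // number of increments
      if (nk < 1) { acc = NA_REAL; break; }
      double s = 0.0;
      for (int i = 1; i <= nk; ++i) {
        s += std::fabs(x[m - 1 + i * k] - x[m - 1 + (i - 1) * k]);
      }
      acc += (s * (double)(N - 1) / ((double)nk * (double)k)) / (double)k;
    }
    L[k - 1] = acc / (double)k;
  }
  return L;
}
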