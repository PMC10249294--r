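#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Chebyshev distance between templates starting at i and j, length m
static inline double cheb(const NumericVector& x, int i, int j, int m) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double a = std::fabs(x[i + k] - x[j + k]);
    if (a > d) d = a;
  }
  return d;
}

// Approximate entropy: Phi(m) - Phi(m+1), self-matches included,
// templates of length m taken at i = 0..n-m.
// [[Rcpp::export]]
double cpp_apen(NumericVector x, int m, double r) {
  int n = x.size();
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    int N = n - mm + 1;
    double acc = 0.0;
    for (int i = 0; i < N; ++i) {
      int cnt = 0;
      for (int j = 0; j < N; ++j)
        if (cheb(x, i, j, mm) <= r) ++cnt;  // includes j == i
      acc += std::log((double)cnt / (double)N);
    }
    phi[s] = acc / (double)N;
  }
  return phi[0] - phi[1];
}

// Sample entropy pair counts: B = matches at length m, A = at m+1,
// over unordered pairs i < j with both templates drawn from the first
// n - m starting positions (so every template has an (m+1)-extension).
// [[Rcpp::export]]
NumericVector cpp_sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int N = n - m;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      if (cheb(x, i, j, m) <= r) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// All pairwise Euclidean distances between delay-embedded vectors
// (dimension m, lag tau); length M*(M-1)/2 with M = n - (m-1)*tau.
// [[Rcpp::export]]
NumericVector cpp_embed_dists(NumericVector x, int m, int tau) {
  int n = x.size();
  int M = n - (m - 1) * tau;
  if (M < 2) stop("too few embedded vectors");
  R_xlen_t np = (R_xlen_t)M * (M - 1) / 2;
  NumericVector out(np);
  R_xlen_t p = 0;
  for (int i = 0; i < M - 1; ++i) {
    for (int j = i + 1; j < M; ++j) {
      double s = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = x[i + k * tau] - x[j + k * tau];
        s += d * d;
      }
      out[p++] = std::sqrt(s);
    }
  }
  return out;
}

// Count of unordered embedded-vector pairs with Euclidean distance <=
// threshold (ties recurrent); used for the recurrence rate without
// materialising the distance matrix.
// [[Rcpp::export]]
double cpp_recurrence_count(NumericVector x, int m, int tau, double threshold) {
  int n = x.size();
  int M = n - (m - 1) * tau;
  if (M < 2) stop("too few embedded vectors");
  double t2 = threshold * threshold;
  double cnt = 0.0;
  for (int i = 0; i < M - 1; ++i) {
    for (int j = i + 1; j < M; ++j) {
      double s = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = x[i + k * tau] - x[j + k * tau];
        s += d * d;
        if (s > t2) break;
      }
      if (s <= t2) cnt += 1.0;
    }
  }
  return cnt;
}
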