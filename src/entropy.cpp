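#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sample entropy via one O(n^2) pass counting template matches at lengths
// 2..4 under the Chebyshev norm (self-matches excluded). Returns
// SampEn(m=2) and SampEn(m=3) for tolerance r; a small floor keeps the
// estimate finite when no (m+1)-templates match.
// [[Rcpp::export]]
NumericVector sampen23_cpp(NumericVector x, double r) {
  int n = x.size();
  const double eps = 1e-12;
  double cnt2 = 0, cnt3 = 0, cnt4 = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int maxk = std::min(4, n - j);
      int k = 0;
      while (k < maxk && std::fabs(x[i + k] - x[j + k]) <= r) ++k;
      if (k >= 2) ++cnt2;
      if (k >= 3) ++cnt3;
      if (k >= 4) ++cnt4;
    }
  }
  NumericVector out(2);
  out[0] = -std::log((cnt3 + eps) / (cnt2 + eps));
  out[1] = -std::log((cnt4 + eps) / (cnt3 + eps));
  return out;
}

// Permutation entropy of order m and delay tau, in bits, optionally
// normalised by log2(m!). Ordinal patterns are ranked by a Lehmer code;
// ties broken by temporal order (stable).
// [[Rcpp::export]]
double perm_entropy_cpp(NumericVector x, int m, int tau, bool normalize) {
  int n = x.size();
  int npat = n - (m - 1) * tau;
  if (npat < 1) stop("window too short for permutation order %d, delay %d", m, tau);
  int nfact = 1;
  for (int i = 2; i <= m; ++i) nfact *= i;
  std::vector<double> freq(nfact, 0.0);
  for (int t = 0; t < npat; ++t) {
    // Lehmer code of the ordinal pattern
    int code = 0;
    for (int i = 1; i < m; ++i) {
      int rank = 0;
      double xi = x[t + i * tau];
      for (int j = 0; j < i; ++j)
        if (x[t + j * tau] <= xi) ++rank;
      code = code * (i + 1) + rank;
    }
    freq[code] += 1.0;
  }
  double H = 0;
  for (int c = 0; c < nfact; ++c) {
    if (freq[c] > 0) {
      double p = freq[c] / npat;
      H -= p * std::log2(p);
    }
  }
  if (normalize) H /= std::log2((double)nfact);
  return H;
}
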