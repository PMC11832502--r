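#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman–Moorman counting scheme).
// Templates of length m start at 0..n-m-1 so every template has an (m+1)-th
// extension; distance is Chebyshev, matches are strict (< r), self-pairs
// excluded. The first coordinate is screened through a sorted index so only
// pairs with |x_i - x_j| < r are ever touched.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int N = n - m;  // number of templates with an extension
  if (N < 2) return NumericVector::create(0.0, 0.0);

  std::vector<int> ord(N);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  double A = 0.0, B = 0.0;
  for (int p = 0; p < N - 1; ++p) {
    const int a = ord[p];
    const double xa = x[a];
    for (int q = p + 1; q < N && x[ord[q]] - xa < r; ++q) {
      const int b = ord[q];
      bool ok = true;
      for (int k = 1; k < m; ++k) {
        if (std::abs(x[a + k] - x[b + k]) >= r) { ok = false; break; }
      }
      if (ok) {
        B += 1.0;
        if (std::abs(x[a + m] - x[b + m]) < r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// Lempel–Ziv 1976 exhaustive-history complexity of a binary sequence,
// Kaspar–Schuster scan. A trailing incomplete word counts as one word.
// [[Rcpp::export(name = ".lz76_count")]]
int lz76_count(IntegerVector s) {
  const int n = s.size();
  if (n == 0) return 0;
  if (n == 1) return 1;
  // 1-based pseudocode; S(j) = s[j-1]. Prefix s[1..l] parsed, word at l+1.
  long c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return static_cast<int>(c);
}
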