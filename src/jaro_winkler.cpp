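#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Jaro similarity of two byte strings (canonical ASCII upper-case input).
static double jaro(const std::string &a, const std::string &b) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la == 0 && lb == 0) return 1.0;
  if (la == 0 || lb == 0) return 0.0;
  const int window = std::max(0, std::max(la, lb) / 2 - 1);

  std::vector<char> amatch(la, 0), bmatch(lb, 0);
  int m = 0;
  for (int i = 0; i < la; ++i) {
    const int lo = std::max(0, i - window);
    const int hi = std::min(lb - 1, i + window);
    for (int j = lo; j <= hi; ++j) {
      if (!bmatch[j] && a[i] == b[j]) {
        amatch[i] = 1; bmatch[j] = 1; ++m;
        break;
      }
    }
  }
  if (m == 0) return 0.0;

  // half-transpositions: matched characters out of order
  int t2 = 0, j = 0;
  for (int i = 0; i < la; ++i) {
    if (!amatch[i]) continue;
    while (!bmatch[j]) ++j;
    if (a[i] != b[j]) ++t2;
    ++j;
  }
  const double t = t2 / 2.0;
  return (m / (double)la + m / (double)lb + (m - t) / m) / 3.0;
}

//' Vectorised Jaro-Winkler similarity (prefix weight p, max prefix length 4).
//' Missing input in either position yields NA.
// [[Rcpp::export(name = ".jaro_winkler_cpp")]]
NumericVector jaro_winkler_cpp(CharacterVector x, CharacterVector y, double p = 0.1) {
  const R_xlen_t n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    if (x[k] == NA_STRING || y[k] == NA_STRING) { out[k] = NA_REAL; continue; }
    const std::string a = as<std::string>(x[k]);
    const std::string b = as<std::string>(y[k]);
    const double dj = jaro(a, b);
    int l = 0;
    const int maxl = std::min((int)std::min(a.size(), b.size()), 4);
    while (l < maxl && a[l] == b[l]) ++l;
    out[k] = dj + l * p * (1.0 - dj);
  }
  return out;
}
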