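#include <Rcpp.h>
using namespace Rcpp;

// Template-matching kernels for sample and fuzzy entropy.
//
// Templates of length m and m+1 are both taken at starting indices
// i = 1..N-m so the two pair sets are comparable (the (m+1)-template at i
// ends at i+m <= N). Counts are over unordered pairs i < j; the A/B ratio
// is unaffected by the choice of ordered vs unordered pairs.

// [[Rcpp::export]]
NumericVector sampen_pair_counts(NumericVector x, int m, double r) {
  const int N = x.size();
  const int n_templ = N - m;
  double B = 0.0, A = 0.0;
  if (n_templ < 2) return NumericVector::create(_["a"] = 0.0, _["b"] = 0.0);
  for (int i = 0; i < n_templ - 1; ++i) {
    for (int j = i + 1; j < n_templ; ++j) {
      double d = 0.0;
      bool within = true;
      for (int k = 0; k < m; ++k) {
        double ad = std::abs(x[i + k] - x[j + k]);
        if (ad > d) d = ad;
        if (d > r) { within = false; break; }
      }
      if (!within) continue;
      B += 1.0;
      double ad = std::abs(x[i + m] - x[j + m]);
      if (ad > d) d = ad;
      if (d <= r) A += 1.0;
    }
  }
  return NumericVector::create(_["a"] = A, _["b"] = B);
}

// [[Rcpp::export]]
NumericVector sampen_fuzzy_counts(NumericVector x, int m, double r, double n) {
  // One pass over template pairs computing both the crisp counts (sample
  // entropy) and the fuzzy membership sums. Exponent n == 2 is the common
  // case and avoids pow().
  const int N = x.size();
  const int n_templ = N - m;
  const bool sq = (n == 2.0);
  double B = 0.0, A = 0.0, Bf = 0.0, Af = 0.0;
  if (n_templ < 2)
    return NumericVector::create(_["a"] = 0.0, _["b"] = 0.0,
                                 _["af"] = 0.0, _["bf"] = 0.0);
  const double inv_r = 1.0 / r;
  // memberships below exp(-60) ~ 9e-27 cannot move the pooled sums at any
  // tolerance in use; skipping them avoids exp() on far pairs
  const double d_cut = r * (sq ? std::sqrt(60.0) : std::pow(60.0, 1.0 / n));
  for (int i = 0; i < n_templ - 1; ++i) {
    for (int j = i + 1; j < n_templ; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double ad = std::abs(x[i + k] - x[j + k]);
        if (ad > d) d = ad;
      }
      if (d > d_cut) continue;
      if (d <= r) B += 1.0;
      double u = d * inv_r;
      Bf += std::exp(sq ? -(u * u) : -std::pow(u, n));
      double ad = std::abs(x[i + m] - x[j + m]);
      if (ad > d) d = ad;
      if (d > d_cut) continue;
      if (d <= r) A += 1.0;
      u = d * inv_r;
      Af += std::exp(sq ? -(u * u) : -std::pow(u, n));
    }
  }
  return NumericVector::create(_["a"] = A, _["b"] = B,
                               _["af"] = Af, _["bf"] = Bf);
}

// [[Rcpp::export]]
NumericVector fuzzy_pair_sums(NumericVector x, int m, double r, double n) {
  const int N = x.size();
  const int n_templ = N - m;
  const bool sq = (n == 2.0);
  const double inv_r = 1.0 / r;
  const double d_cut = r * (sq ? std::sqrt(60.0) : std::pow(60.0, 1.0 / n));
  double B = 0.0, A = 0.0;
  if (n_templ < 2) return NumericVector::create(_["a"] = 0.0, _["b"] = 0.0);
  for (int i = 0; i < n_templ - 1; ++i) {
    for (int j = i + 1; j < n_templ; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double ad = std::abs(x[i + k] - x[j + k]);
        if (ad > d) d = ad;
      }
      if (d > d_cut) continue;
      double u = d * inv_r;
      B += std::exp(sq ? -(u * u) : -std::pow(u, n));
      double ad = std::abs(x[i + m] - x[j + m]);
      if (ad > d) d = ad;
      if (d > d_cut) continue;
      u = d * inv_r;
      A += std::exp(sq ? -(u * u) : -std::pow(u, n));
    }
  }
  return NumericVector::create(_["a"] = A, _["b"] = B);
}
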