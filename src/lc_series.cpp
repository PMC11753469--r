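#include <Rcpp.h>

// Probability mass function of a compound-Poisson distribution from the power
// series of its cumulant generating function: given g(z) = sum_k g_k z^k with
// g_k >= 0 for k >= 1, the pmf of the distribution with pgf exp(g(z) - g(1))
// ... more precisely with pgf H(z) = exp(g(z)) where g(0) = log P(0), obeys
//   p_0 = exp(g_0),  p_k = (1/k) * sum_{j=1..k} j * g_j * p_{k-j}.
// All terms are non-negative, so the recursion is numerically stable.
// [[Rcpp::export(name = ".lc_pmf_series")]]
Rcpp::NumericVector lc_pmf_series(Rcpp::NumericVector g) {
  const int K = g.size() - 1;
  Rcpp::NumericVector p(K + 1);
  p[0] = std::exp(g[0]);
  for (int k = 1; k <= K; ++k) {
    double s = 0.0;
    for (int j = 1; j <= k; ++j) s += j * g[j] * p[k - j];
    p[k] = s / k;
  }
  return p;
}
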