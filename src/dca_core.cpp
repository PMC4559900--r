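#include <Rcpp.h>
using namespace Rcpp;

// Sequence reweighting: weight(s) = 1 / #{t : identity(s,t) >= theta}.
// msa is M x L, integer states in 0..q-1 (gap included in identity counts).
// [[Rcpp::export]]
NumericVector cpp_seq_weights(IntegerMatrix msa, double theta) {
  const int M = msa.nrow(), L = msa.ncol();
  IntegerVector nb(M, 1); // self counts
  for (int s = 0; s < M; ++s) {
    for (int t = s + 1; t < M; ++t) {
      int id = 0;
      for (int c = 0; c < L; ++c)
        if (msa(s, c) == msa(t, c)) ++id;
      if ((double)id / L >= theta) { ++nb[s]; ++nb[t]; }
    }
  }
  NumericVector w(M);
  for (int s = 0; s < M; ++s) w[s] = 1.0 / nb[s];
  return w;
}

// Pseudocount-regularised single and pair frequencies.
// Returns f_i as L x q and f_ij as (L*q) x (L*q) with block (i,j) holding
// f_ij(a,b) at [i*q + a, j*q + b]. Diagonal blocks follow the convention
// f_ii(a,b) = delta_ab * f_i(a).
// [[Rcpp::export]]
List cpp_frequencies(IntegerMatrix msa, NumericVector w, double lambda, int q) {
  const int M = msa.nrow(), L = msa.ncol();
  double meff = 0.0;
  for (int s = 0; s < M; ++s) meff += w[s];
  const double denom1 = lambda + meff;
  NumericMatrix fi(L, q);
  std::fill(fi.begin(), fi.end(), lambda / q / denom1);
  NumericMatrix fij(L * q, L * q);
  std::fill(fij.begin(), fij.end(), lambda / (double)(q * q) / denom1);
  for (int s = 0; s < M; ++s) {
    const double ws = w[s] / denom1;
    for (int i = 0; i < L; ++i) {
      const int a = msa(s, i);
      fi(i, a) += ws;
      for (int j = i + 1; j < L; ++j) {
        const int b = msa(s, j);
        fij(i * q + a, j * q + b) += ws;
        fij(j * q + b, i * q + a) += ws;
      }
    }
  }
  // diagonal blocks: f_ii(a,b) = delta_ab f_i(a)
  for (int i = 0; i < L; ++i)
    for (int a = 0; a < q; ++a)
      for (int b = 0; b < q; ++b)
        fij(i * q + a, i * q + b) = (a == b) ? fi(i, a) : 0.0;
  return List::create(_["f_i"] = fi, _["f_ij"] = fij, _["Meff"] = meff);
}
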