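#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Single-site Gibbs sampler for a sparse-coupling Potts model.
// h: L x q fields; pairs: K x 2 (0-based, i < j); J: list of K q x q
// matrices; beta: inverse temperature. One chain, `burn_in` sweeps of
// equilibration, then M samples taken every `thin` sweeps.
// Energy convention: E(s) = -sum_i h_i(s_i) - sum_(ij) J_ij(s_i, s_j),
// so larger h/J favour a state and beta multiplies both.
// [[Rcpp::export]]
IntegerMatrix cpp_sample_potts(int L, int q, NumericMatrix h,
                               IntegerMatrix pairs, List J,
                               double beta, int M, int burn_in, int thin,
                               int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  const int K = pairs.nrow();
  // adjacency: for each site, list of (pair index, is_first_member)
  std::vector<std::vector<std::pair<int, bool> > > adj(L);
  std::vector<NumericMatrix> Jm;
  for (int k = 0; k < K; ++k) {
    adj[pairs(k, 0)].push_back(std::make_pair(k, true));
    adj[pairs(k, 1)].push_back(std::make_pair(k, false));
    Jm.push_back(as<NumericMatrix>(J[k]));
  }

  std::vector<int> s(L);
  for (int i = 0; i < L; ++i)
    s[i] = (int)(unif(rng) * q) % q;

  std::vector<double> logp(q), p(q);
  auto sweep = [&]() {
    for (int i = 0; i < L; ++i) {
      double mx = -1e300;
      for (int a = 0; a < q; ++a) {
        double e = h(i, a);
        for (size_t t = 0; t < adj[i].size(); ++t) {
          const int k = adj[i][t].first;
          const NumericMatrix &Jk = Jm[k];
          if (adj[i][t].second) e += Jk(a, s[pairs(k, 1)]);
          else                  e += Jk(s[pairs(k, 0)], a);
        }
        logp[a] = beta * e;
        if (logp[a] > mx) mx = logp[a];
      }
      double z = 0.0;
      for (int a = 0; a < q; ++a) { p[a] = std::exp(logp[a] - mx); z += p[a]; }
      double u = unif(rng) * z, cum = 0.0;
      int pick = q - 1;
      for (int a = 0; a < q; ++a) { cum += p[a]; if (u <= cum) { pick = a; break; } }
      s[i] = pick;
    }
  };

  for (int b = 0; b < burn_in; ++b) sweep();
  IntegerMatrix out(M, L);
  for (int m = 0; m < M; ++m) {
    for (int t = 0; t < thin; ++t) sweep();
    for (int i = 0; i < L; ++i) out(m, i) = s[i];
  }
  return out;
}
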