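#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for a pairwise Potts model with site fields h (L x q) and
// "planted" couplings J_ij(a,b) = strength * 1[a == b] on a sparse pair list.
// States are 0-based internally; sampling uses R's RNG so results are fully
// determined by set.seed() on the R side.
//
// One long chain: burn-in sweeps, then record every `thin` sweeps.
// [[Rcpp::export]]
IntegerMatrix potts_gibbs_cpp(int L, int q, NumericMatrix h,
                              IntegerMatrix pairs, NumericVector strength,
                              int n_samples, int burnin, int thin) {
  IntegerMatrix out(n_samples, L);
  std::vector<int> state(L);

  // adjacency: partners[i] lists (j, strength)
  std::vector<std::vector<std::pair<int, double> > > partners(L);
  for (int p = 0; p < pairs.nrow(); ++p) {
    int i = pairs(p, 0), j = pairs(p, 1);
    partners[i].push_back(std::make_pair(j, strength[p]));
    partners[j].push_back(std::make_pair(i, strength[p]));
  }

  for (int i = 0; i < L; ++i) state[i] = (int)(unif_rand() * q) % q;

  std::vector<double> logp(q), prob(q);
  long total_sweeps = (long)burnin + (long)n_samples * thin;
  int recorded = 0;
  for (long sweep = 0; sweep < total_sweeps && recorded < n_samples; ++sweep) {
    for (int i = 0; i < L; ++i) {
      double mx = -1e300;
      for (int a = 0; a < q; ++a) {
        double e = h(i, a);
        for (size_t t = 0; t < partners[i].size(); ++t) {
          if (state[partners[i][t].first] == a) e += partners[i][t].second;
        }
        logp[a] = e;
        if (e > mx) mx = e;
      }
      double z = 0.0;
      for (int a = 0; a < q; ++a) { prob[a] = std::exp(logp[a] - mx); z += prob[a]; }
      double u = unif_rand() * z, c = 0.0;
      int pick = q - 1;
      for (int a = 0; a < q; ++a) { c += prob[a]; if (u <= c) { pick = a; break; } }
      state[i] = pick;
    }
    if (sweep >= burnin && ((sweep - burnin) % thin) == (thin - 1)) {
      for (int i = 0; i < L; ++i) out(recorded, i) = state[i] + 1; // 1-based states
      ++recorded;
    }
  }
  return out;
}

// Identity-based sequence weights: w_m = 1 / #{m' : identity(m, m') >= thr},
// self included. msa is an n x L integer matrix of state codes.
// [[Rcpp::export]]
NumericVector seq_weights_cpp(IntegerMatrix msa, double thr) {
  int n = msa.nrow(), L = msa.ncol();
  std::vector<int> cnt(n, 1); // self
  int need = (int)std::ceil(thr * L - 1e-9);
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      int match = 0;
      for (int c = 0; c < L; ++c) if (msa(a, c) == msa(b, c)) ++match;
      if (match >= need) { ++cnt[a]; ++cnt[b]; }
    }
  }
  NumericVector w(n);
  for (int a = 0; a < n; ++a) w[a] = 1.0 / cnt[a];
  return w;
}
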