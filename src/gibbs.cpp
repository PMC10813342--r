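#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA.
//
// docs: list of integer vectors, 0-based vocabulary ids per token.
// Returns the final-state count matrices; point estimates (phi, theta) are
// formed on the R side. Uses R's RNG stream, so results are reproducible
// from set.seed() alone.
// [[Rcpp::export]]
List gibbs_lda(List docs, int K, int V, double alpha, double beta,
               int iterations) {
  int D = docs.size();
  std::vector<std::vector<int>> w(D);
  int total_tokens = 0;
  for (int d = 0; d < D; ++d) {
    IntegerVector dv = docs[d];
    w[d].assign(dv.begin(), dv.end());
    total_tokens += dv.size();
  }

  IntegerMatrix ndk(D, K);   // doc-topic counts
  IntegerMatrix nkw(K, V);   // topic-word counts
  IntegerVector nk(K);       // topic totals
  std::vector<std::vector<int>> z(D);

  RNGScope scope;

  // random initial assignments
  for (int d = 0; d < D; ++d) {
    int m = w[d].size();
    z[d].resize(m);
    for (int i = 0; i < m; ++i) {
      int t = (int)(unif_rand() * K);
      if (t == K) t = K - 1;
      z[d][i] = t;
      ndk(d, t)++; nkw(t, w[d][i])++; nk[t]++;
    }
  }

  std::vector<double> p(K);
  double Vbeta = V * beta;

  for (int iter = 0; iter < iterations; ++iter) {
    for (int d = 0; d < D; ++d) {
      int m = w[d].size();
      for (int i = 0; i < m; ++i) {
        int v = w[d][i];
        int t = z[d][i];
        ndk(d, t)--; nkw(t, v)--; nk[t]--;
        double cum = 0.0;
        for (int k = 0; k < K; ++k) {
          cum += (ndk(d, k) + alpha) * (nkw(k, v) + beta) / (nk[k] + Vbeta);
          p[k] = cum;
        }
        double u = unif_rand() * cum;
        int tnew = 0;
        while (tnew < K - 1 && p[tnew] < u) ++tnew;
        z[d][i] = tnew;
        ndk(d, tnew)++; nkw(tnew, v)++; nk[tnew]++;
      }
    }
    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["ndk"] = ndk, _["nkw"] = nkw, _["nk"] = nk,
                      _["total_tokens"] = total_tokens);
}
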