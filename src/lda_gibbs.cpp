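#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
// docs: list of 0-based integer word-id vectors, one per document.
// Uses R's RNG stream, so results are reproducible under set.seed().
// [[Rcpp::export(name = ".lda_gibbs_cpp")]]
List lda_gibbs_cpp(List docs, int n_vocab, int n_topics,
                   double alpha, double beta, int n_iter) {
  int D = docs.size();
  int K = n_topics;
  int V = n_vocab;

  std::vector<std::vector<int>> w(D), z(D);
  IntegerMatrix nwk(V, K);   // word-topic counts
  IntegerMatrix ndk(D, K);   // doc-topic counts
  IntegerVector nk(K);       // tokens per topic
  IntegerVector nd(D);       // tokens per doc

  RNGScope scope;

  for (int d = 0; d < D; ++d) {
    IntegerVector doc = docs[d];
    int n = doc.size();
    w[d].resize(n);
    z[d].resize(n);
    nd[d] = n;
    for (int i = 0; i < n; ++i) {
      int wid = doc[i];
      int k = (int)(unif_rand() * K);
      if (k == K) k = K - 1;
      w[d][i] = wid;
      z[d][i] = k;
      ++nwk(wid, k);
      ++ndk(d, k);
      ++nk[k];
    }
  }

  std::vector<double> p(K);
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int d = 0; d < D; ++d) {
      int n = nd[d];
      for (int i = 0; i < n; ++i) {
        int wid = w[d][i];
        int k = z[d][i];
        --nwk(wid, k); --ndk(d, k); --nk[k];
        double total = 0.0;
        for (int t = 0; t < K; ++t) {
          p[t] = (nwk(wid, t) + beta) / (nk[t] + V * beta) *
                 (ndk(d, t) + alpha);
          total += p[t];
        }
        double u = unif_rand() * total;
        double cum = 0.0;
        int knew = K - 1;
        for (int t = 0; t < K; ++t) {
          cum += p[t];
          if (u <= cum) { knew = t; break; }
        }
        z[d][i] = knew;
        ++nwk(wid, knew); ++ndk(d, knew); ++nk[knew];
      }
    }
  }

  return List::create(_["nwk"] = nwk, _["ndk"] = ndk,
                      _["nk"] = nk, _["nd"] = nd);
}
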