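#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation with symmetric
// Dirichlet priors. Single-threaded and deterministically seeded.

namespace {
struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 0x2545F4914F6CDD1DULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};
} // namespace

// docs: list of integer vectors of 0-based vocabulary indices.
// Returns doc_topic (D x K, posterior mean) and topic_term (K x V).
// [[Rcpp::export(name = ".lda_gibbs")]]
List lda_gibbs(List docs, int V, int K, double alpha, double beta,
               int iters, int seed) {
  const int D = docs.size();
  XorShift64 rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL);

  std::vector<std::vector<int>> z(D);
  std::vector<int> nwk(static_cast<size_t>(V) * K, 0);
  std::vector<int> ndk(static_cast<size_t>(D) * K, 0);
  std::vector<long long> nk(K, 0);

  for (int d = 0; d < D; ++d) {
    IntegerVector doc = docs[d];
    z[d].resize(doc.size());
    for (int i = 0; i < doc.size(); ++i) {
      int t = static_cast<int>(rng.unif() * K);
      if (t >= K) t = K - 1;
      z[d][i] = t;
      ++nwk[static_cast<size_t>(doc[i]) * K + t];
      ++ndk[static_cast<size_t>(d) * K + t];
      ++nk[t];
    }
  }

  std::vector<double> p(K);
  const double Vbeta = V * beta;

  for (int it = 0; it < iters; ++it) {
    for (int d = 0; d < D; ++d) {
      IntegerVector doc = docs[d];
      for (int i = 0; i < doc.size(); ++i) {
        const int w = doc[i];
        const int told = z[d][i];
        --nwk[static_cast<size_t>(w) * K + told];
        --ndk[static_cast<size_t>(d) * K + told];
        --nk[told];
        double cum = 0.0;
        for (int t = 0; t < K; ++t) {
          cum += (nwk[static_cast<size_t>(w) * K + t] + beta) /
                 (nk[t] + Vbeta) *
                 (ndk[static_cast<size_t>(d) * K + t] + alpha);
          p[t] = cum;
        }
        const double u = rng.unif() * cum;
        int tnew = 0;
        while (tnew < K - 1 && p[tnew] < u) ++tnew;
        z[d][i] = tnew;
        ++nwk[static_cast<size_t>(w) * K + tnew];
        ++ndk[static_cast<size_t>(d) * K + tnew];
        ++nk[tnew];
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix doc_topic(D, K);
  for (int d = 0; d < D; ++d) {
    IntegerVector doc = docs[d];
    const double denom = doc.size() + K * alpha;
    for (int t = 0; t < K; ++t)
      doc_topic(d, t) = (ndk[static_cast<size_t>(d) * K + t] + alpha) / denom;
  }
  NumericMatrix topic_term(K, V);
  for (int t = 0; t < K; ++t)
    for (int w = 0; w < V; ++w)
      topic_term(t, w) = (nwk[static_cast<size_t>(w) * K + t] + beta) / (nk[t] + Vbeta);

  return List::create(_["doc_topic"] = doc_topic, _["topic_term"] = topic_term);
}
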