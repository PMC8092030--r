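#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Skip-gram with negative sampling (SGNS), single-threaded so that a fixed
// seed yields bit-identical vectors on every run. Layout follows the classic
// word2vec training loop: one input matrix (returned) and one output matrix
// for the negative-sampling objective.

namespace {

struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  uint64_t below(uint64_t n) { return next() % n; }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// docs: list of integer vectors of 0-based vocabulary indices.
// counts: vocabulary frequencies (length V), used for the 0.75-power
// unigram table that negative samples are drawn from.
// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List docs, int V, NumericVector counts, int d,
                         int window, int negative, int epochs,
                         double alpha0, int seed) {
  if (V < 1) stop("empty vocabulary");
  XorShift64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  std::vector<double> syn0(static_cast<size_t>(V) * d);
  std::vector<double> syn1(static_cast<size_t>(V) * d, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / d;

  // unigram table, power 0.75
  const int table_size = 1 << 20;
  std::vector<int> table(table_size);
  double total = 0.0;
  for (int v = 0; v < V; ++v) total += std::pow(counts[v], 0.75);
  double cum = std::pow(counts[0], 0.75) / total;
  int v = 0;
  for (int i = 0; i < table_size; ++i) {
    table[i] = v;
    if (static_cast<double>(i) / table_size > cum && v < V - 1) {
      ++v;
      cum += std::pow(counts[v], 0.75) / total;
    }
  }

  // count total training positions for the linear learning-rate decay
  long long total_words = 0;
  for (R_xlen_t di = 0; di < docs.size(); ++di)
    total_words += Rf_xlength(docs[di]);
  const long long total_steps = total_words * static_cast<long long>(epochs);
  long long trained = 0;

  std::vector<double> grad(d);

  for (int ep = 0; ep < epochs; ++ep) {
    for (R_xlen_t di = 0; di < docs.size(); ++di) {
      IntegerVector doc = docs[di];
      const int n = doc.size();
      for (int pos = 0; pos < n; ++pos, ++trained) {
        double alpha = alpha0 * (1.0 - static_cast<double>(trained) / (total_steps + 1));
        if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
        const int center = doc[pos];
        const int b = static_cast<int>(rng.below(static_cast<uint64_t>(window))); // dynamic window
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          const int cpos = pos + off;
          if (cpos < 0 || cpos >= n) continue;
          const int context = doc[cpos];
          double* w_in = &syn0[static_cast<size_t>(context) * d];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = center;
              label = 1.0;
            } else {
              target = table[rng.below(table_size)];
              if (target == center) continue;
              label = 0.0;
            }
            double* w_out = &syn1[static_cast<size_t>(target) * d];
            double f = 0.0;
            for (int j = 0; j < d; ++j) f += w_in[j] * w_out[j];
            const double g = (label - sigmoid(f)) * alpha;
            for (int j = 0; j < d; ++j) {
              grad[j] += g * w_out[j];
              w_out[j] += g * w_in[j];
            }
          }
          for (int j = 0; j < d; ++j) w_in[j] += grad[j];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(V, d);
  for (int vv = 0; vv < V; ++vv)
    for (int j = 0; j < d; ++j) out(vv, j) = syn0[static_cast<size_t>(vv) * d + j];
  return out;
}
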