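#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Deterministic single-threaded trainer for CBOW / skip-gram with
// negative sampling. All randomness comes from an internal xorshift64*
// generator seeded explicitly, so identical configs give identical
// vector tables on every platform.

namespace {

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t x = state;
    x ^= x >> 12;
    x ^= x << 25;
    x ^= x >> 27;
    state = x;
    return x * 0x2545F4914F6CDD1DULL;
  }
  double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  int sample_cum(const std::vector<double>& cum) {
    double u = unif() * cum.back();
    int lo = 0, hi = (int)cum.size() - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] <= u) lo = mid + 1; else hi = mid;
    }
    return lo;
  }
};

inline double sigmoid(double x) {
  if (x > 6.0) return 1.0 - 1e-8;
  if (x < -6.0) return 1e-8;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, int vocab_size,
                         NumericVector noise_weights, bool cbow, int dim,
                         int window, int negative, int epochs, double alpha0,
                         int seed) {
  const int V = vocab_size;
  const int D = dim;
  Rng rng((uint64_t)seed * 2654435761ULL + 1ULL);

  // cumulative noise distribution for negative sampling
  std::vector<double> cum(V);
  double acc = 0.0;
  for (int i = 0; i < V; ++i) {
    acc += noise_weights[i];
    cum[i] = acc;
  }

  // copy sentences to 0-based int vectors; -1 marks out-of-vocabulary
  std::vector<std::vector<int> > sents(sentences.size());
  long long total_words = 0;
  for (int s = 0; s < sentences.size(); ++s) {
    IntegerVector iv = sentences[s];
    sents[s].resize(iv.size());
    for (int t = 0; t < iv.size(); ++t) {
      sents[s][t] = (iv[t] == NA_INTEGER) ? -1 : iv[t] - 1;
      if (sents[s][t] >= 0) ++total_words;
    }
  }

  std::vector<double> syn0((size_t)V * D);   // input vectors (returned)
  std::vector<double> syn1((size_t)V * D, 0.0);  // output vectors
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / D;

  std::vector<double> neu1(D), neu1e(D);
  std::vector<int> ctx;
  ctx.reserve(2 * window);

  const double total_steps = (double)total_words * epochs + 1.0;
  long long processed = 0;
  double lr = alpha0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t s = 0; s < sents.size(); ++s) {
      const std::vector<int>& sent = sents[s];
      const int len = (int)sent.size();
      for (int t = 0; t < len; ++t) {
        const int wt = sent[t];
        if (wt < 0) continue;
        ++processed;
        lr = alpha0 * std::max(1e-4, 1.0 - (double)processed / total_steps);

        ctx.clear();
        for (int j = t - window; j <= t + window; ++j) {
          if (j == t || j < 0 || j >= len) continue;
          if (sent[j] >= 0) ctx.push_back(sent[j]);
        }
        if (ctx.empty()) continue;

        if (cbow) {
          // hidden vector: mean of context input vectors
          std::fill(neu1.begin(), neu1.end(), 0.0);
          for (int c : ctx)
            for (int k = 0; k < D; ++k) neu1[k] += syn0[(size_t)c * D + k];
          const double inv = 1.0 / ctx.size();
          for (int k = 0; k < D; ++k) neu1[k] *= inv;

          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) { target = wt; label = 1.0; }
            else {
              target = rng.sample_cum(cum);
              if (target == wt) continue;
              label = 0.0;
            }
            double* out = &syn1[(size_t)target * D];
            double f = 0.0;
            for (int k = 0; k < D; ++k) f += neu1[k] * out[k];
            const double g = (label - sigmoid(f)) * lr;
            for (int k = 0; k < D; ++k) neu1e[k] += g * out[k];
            for (int k = 0; k < D; ++k) out[k] += g * neu1[k];
          }
          // exact gradient of the mean formulation
          for (int c : ctx) {
            double* in = &syn0[(size_t)c * D];
            for (int k = 0; k < D; ++k) in[k] += neu1e[k] * inv;
          }
        } else {
          // skip-gram: current word as input predicts each context word
          double* in = &syn0[(size_t)wt * D];
          for (int c : ctx) {
            std::fill(neu1e.begin(), neu1e.end(), 0.0);
            for (int d = 0; d <= negative; ++d) {
              int target;
              double label;
              if (d == 0) { target = c; label = 1.0; }
              else {
                target = rng.sample_cum(cum);
                if (target == c) continue;
                label = 0.0;
              }
              double* out = &syn1[(size_t)target * D];
              double f = 0.0;
              for (int k = 0; k < D; ++k) f += in[k] * out[k];
              const double g = (label - sigmoid(f)) * lr;
              for (int k = 0; k < D; ++k) neu1e[k] += g * out[k];
              for (int k = 0; k < D; ++k) out[k] += g * in[k];
            }
            for (int k = 0; k < D; ++k) in[k] += neu1e[k];
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix result(V, D);
  for (int i = 0; i < V; ++i)
    for (int k = 0; k < D; ++k) result(i, k) = syn0[(size_t)i * D + k];
  return result;
}
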