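// Seeded, single-threaded skip-gram trainer with negative sampling.
// Tokens are 0-based vocabulary indices; the caller owns the vocabulary.
#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
NumericMatrix slp_skipgram_train(List sentences, int vocab_size, int dim,
                                 int window, int epochs, int negative,
                                 double alpha, int seed) {
  if (vocab_size <= 0) stop("empty vocabulary");
  std::mt19937_64 rng(static_cast<uint64_t>(seed) + 0x9E3779B97F4A7C15ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // unigram^0.75 cumulative table for negative sampling
  std::vector<double> counts(vocab_size, 0.0);
  long long total_tokens = 0;
  for (int s = 0; s < sentences.size(); ++s) {
    IntegerVector sent = sentences[s];
    total_tokens += sent.size();
    for (int i = 0; i < sent.size(); ++i) {
      int w = sent[i];
      if (w < 0 || w >= vocab_size) stop("token id out of range");
      counts[w] += 1.0;
    }
  }
  if (total_tokens == 0) stop("empty corpus");
  std::vector<double> cum(vocab_size);
  double acc = 0.0;
  for (int v = 0; v < vocab_size; ++v) {
    acc += std::pow(counts[v], 0.75);
    cum[v] = acc;
  }
  const double cum_total = acc;
  auto sample_negative = [&]() -> int {
    double r = unif(rng) * cum_total;
    int lo = 0, hi = vocab_size - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < r) lo = mid + 1; else hi = mid;
    }
    return lo;
  };

  std::vector<double> win((size_t)vocab_size * dim);
  std::vector<double> wout((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < win.size(); ++i)
    win[i] = (unif(rng) - 0.5) / dim;

  const double alpha_min = alpha * 1e-4;
  const double total_words = (double)total_tokens * epochs;
  long long words_done = 0;
  std::vector<double> grad_in(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      const int n = sent.size();
      for (int c = 0; c < n; ++c) {
        double lr = alpha * (1.0 - (double)words_done / (total_words + 1.0));
        if (lr < alpha_min) lr = alpha_min;
        ++words_done;
        const int center = sent[c];
        double* vin = &win[(size_t)center * dim];
        for (int off = -window; off <= window; ++off) {
          if (off == 0) continue;
          const int j = c + off;
          if (j < 0 || j >= n) continue;
          const int context = sent[j];
          std::fill(grad_in.begin(), grad_in.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target; double label;
            if (d == 0) { target = context; label = 1.0; }
            else {
              target = sample_negative();
              if (target == context) continue;
              label = 0.0;
            }
            double* vout = &wout[(size_t)target * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += vin[k] * vout[k];
            const double g = (label - sigmoid(dot)) * lr;
            for (int k = 0; k < dim; ++k) {
              grad_in[k] += g * vout[k];
              vout[k] += g * vin[k];
            }
          }
          for (int k = 0; k < dim; ++k) vin[k] += grad_in[k];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int k = 0; k < dim; ++k)
      out(v, k) = win[(size_t)v * dim + k];
  return out;
}
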