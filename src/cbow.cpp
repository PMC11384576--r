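#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Minimal deterministic xorshift64* generator so training is reproducible
// independently of R's RNG state and of thread scheduling (single-threaded).
static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 2685821657736338717ULL;
}

static inline double runif01(uint64_t &s) {
  return (xorshift64(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// CBOW with negative sampling, word2vec-style: predict the centre word from
// the mean of its context vectors. Returns the input-layer vectors (one row
// per vocabulary word).
//
// sentences: list of integer vectors of 0-based vocabulary indices
//            (out-of-vocabulary tokens already removed upstream)
// counts:    vocabulary frequencies, used for the unigram^0.75 negative table
// [[Rcpp::export(name = ".cbow_train_cpp")]]
NumericMatrix cbow_train_cpp(List sentences, IntegerVector counts, int dim,
                             int window, int epochs, int negative,
                             double alpha, int seed) {
  const int V = counts.size();
  if (V == 0) stop("empty vocabulary");

  uint64_t rng = static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL;
  // avoid the all-zero state
  if (rng == 0) rng = 88172645463325252ULL;

  std::vector<double> syn0(static_cast<size_t>(V) * dim);
  std::vector<double> syn1(static_cast<size_t>(V) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (runif01(rng) - 0.5) / dim;

  // unigram^0.75 table for negative sampling
  const int table_size = 100000;
  std::vector<int> table(table_size);
  double total = 0.0;
  for (int i = 0; i < V; ++i) total += std::pow((double)counts[i], 0.75);
  {
    int i = 0;
    double cum = std::pow((double)counts[0], 0.75) / total;
    for (int a = 0; a < table_size; ++a) {
      table[a] = i;
      if ((a + 1.0) / table_size > cum && i < V - 1) {
        ++i;
        cum += std::pow((double)counts[i], 0.75) / total;
      }
    }
  }

  // total training words for the learning-rate schedule
  long long total_words = 0;
  const int n_sent = sentences.size();
  for (int s = 0; s < n_sent; ++s)
    total_words += as<IntegerVector>(sentences[s]).size();
  if (total_words == 0) stop("no trainable tokens");
  const long long train_total = (long long)epochs * total_words + 1;

  std::vector<double> hidden(dim), grad(dim);
  long long words_done = 0;
  const double min_alpha = alpha * 1e-4;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      IntegerVector sent = sentences[s];
      const int len = sent.size();
      for (int pos = 0; pos < len; ++pos) {
        ++words_done;
        double lr = alpha * (1.0 - (double)words_done / train_total);
        if (lr < min_alpha) lr = min_alpha;

        const int target = sent[pos];
        // reduced window, as in the reference implementation
        const int b = (int)(xorshift64(rng) % (uint64_t)window);
        int cw = 0;
        std::fill(hidden.begin(), hidden.end(), 0.0);
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          const int p = pos + off;
          if (p < 0 || p >= len) continue;
          const double *v = &syn0[(size_t)sent[p] * dim];
          for (int d = 0; d < dim; ++d) hidden[d] += v[d];
          ++cw;
        }
        if (cw == 0) continue;
        for (int d = 0; d < dim; ++d) hidden[d] /= cw;

        std::fill(grad.begin(), grad.end(), 0.0);
        for (int n = 0; n <= negative; ++n) {
          int label, tgt;
          if (n == 0) {
            tgt = target;
            label = 1;
          } else {
            tgt = table[xorshift64(rng) % (uint64_t)table_size];
            if (tgt == target) continue;
            label = 0;
          }
          double *w1 = &syn1[(size_t)tgt * dim];
          double f = 0.0;
          for (int d = 0; d < dim; ++d) f += hidden[d] * w1[d];
          const double g = (label - sigmoid(f)) * lr;
          for (int d = 0; d < dim; ++d) {
            grad[d] += g * w1[d];
            w1[d] += g * hidden[d];
          }
        }
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          const int p = pos + off;
          if (p < 0 || p >= len) continue;
          double *v = &syn0[(size_t)sent[p] * dim];
          for (int d = 0; d < dim; ++d) v[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(V, dim);
  for (int i = 0; i < V; ++i)
    for (int d = 0; d < dim; ++d) out(i, d) = syn0[(size_t)i * dim + d];
  return out;
}
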