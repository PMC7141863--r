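// Skip-gram with negative sampling, single-threaded and fully
// deterministic given the seed (own xorshift RNG; R's RNG is not
// touched).  Sentences arrive as 0-based integer vectors over a fixed
// vocabulary; the unigram counts drive the 0.75-power negative table.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s;
}

static inline double unif01(uint64_t &s) {
  return (xorshift64(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List sentences, int vocab_size, int dim,
                             int window, int negative, int epochs,
                             double alpha, double min_alpha, double sample,
                             NumericVector counts, double seed,
                             IntegerVector init_idx, NumericMatrix init_vec) {
  uint64_t rng = (uint64_t)seed * 2654435761ULL + 1442695040888963407ULL;
  if (rng == 0) rng = 88172645463325252ULL;
  for (int i = 0; i < 16; ++i) xorshift64(rng);  // decorrelate small seeds

  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = (unif01(rng) - 0.5) / dim;
  }
  // warm start: overwrite chosen rows (two-phase/background training)
  for (int k = 0; k < init_idx.size(); ++k) {
    int row = init_idx[k];  // 0-based
    for (int d = 0; d < dim; ++d) {
      syn0[(size_t)row * dim + d] = init_vec(k, d);
    }
  }

  // cumulative unigram^0.75 table for negative sampling (binary search)
  std::vector<double> cum(vocab_size);
  double tot = 0.0;
  for (int i = 0; i < vocab_size; ++i) {
    tot += std::pow((double)counts[i], 0.75);
    cum[i] = tot;
  }

  int n_sent = sentences.size();
  std::vector<std::vector<int>> sents(n_sent);
  long long total_tokens = 0;
  for (int s = 0; s < n_sent; ++s) {
    IntegerVector iv = sentences[s];
    sents[s].assign(iv.begin(), iv.end());
    total_tokens += iv.size();
  }
  long long planned = total_tokens * (long long)epochs;
  if (planned < 1) planned = 1;
  long long done = 0;

  // frequent-word subsampling: keep an occurrence of token w with
  // probability (sqrt(f/t) + 1) * t / f, f its corpus frequency share
  std::vector<double> keep_prob(vocab_size, 1.0);
  if (sample > 0) {
    for (int i = 0; i < vocab_size; ++i) {
      double f = (double)counts[i] / (double)total_tokens;
      double p = (std::sqrt(f / sample) + 1.0) * sample / f;
      keep_prob[i] = p < 1.0 ? p : 1.0;
    }
  }

  std::vector<double> grad_in(dim);
  std::vector<int> kept;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      const std::vector<int> &raw = sents[s];
      kept.clear();
      for (size_t u = 0; u < raw.size(); ++u) {
        ++done;  // lr decays over raw tokens, kept or not
        if (keep_prob[raw[u]] >= 1.0 || unif01(rng) < keep_prob[raw[u]]) {
          kept.push_back(raw[u]);
        }
      }
      const std::vector<int> &sent = kept;
      int n = (int)sent.size();
      for (int i = 0; i < n; ++i) {
        double lr = alpha * (1.0 - (double)done / (double)planned);
        if (lr < min_alpha) lr = min_alpha;
        int center = sent[i];
        int b = (int)(xorshift64(rng) % (uint64_t)window);  // shrunk window
        for (int j = i - window + b; j <= i + window - b; ++j) {
          if (j == i || j < 0 || j >= n) continue;
          int ctx = sent[j];
          double *v_in = &syn0[(size_t)ctx * dim];
          for (int d = 0; d < dim; ++d) grad_in[d] = 0.0;
          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = center;
              label = 1.0;
            } else {
              double r = unif01(rng) * tot;
              int lo = 0, hi = vocab_size - 1;
              while (lo < hi) {
                int mid = (lo + hi) / 2;
                if (cum[mid] < r) lo = mid + 1; else hi = mid;
              }
              target = lo;
              if (target == center) continue;
              label = 0.0;
            }
            double *v_out = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v_in[d] * v_out[d];
            double g = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad_in[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += grad_in[d];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int i = 0; i < vocab_size; ++i) {
    for (int d = 0; d < dim; ++d) out(i, d) = syn0[(size_t)i * dim + d];
  }
  return out;
}
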