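#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with uniform negative sampling over a single shared vector table.
// sequences: list of 1-based integer vectors; context = positions per side;
// learning rate decays linearly from alpha to alpha_min over all pairs.
// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List sequences, int vocab_size, int dim,
                             int context, int negative, int epochs,
                             double alpha, double alpha_min, int seed) {
  const int n_seq = sequences.size();
  std::vector<std::vector<int>> seqs(n_seq);
  long long total_pairs = 0;
  for (int i = 0; i < n_seq; ++i) {
    IntegerVector s = sequences[i];
    seqs[i].assign(s.begin(), s.end());
    for (int &x : seqs[i]) --x;  // 0-based
    const int n = seqs[i].size();
    for (int pos = 0; pos < n; ++pos) {
      int lo = std::max(0, pos - context), hi = std::min(n - 1, pos + context);
      total_pairs += hi - lo;  // window minus the center itself
    }
  }
  if (total_pairs == 0) stop("nothing to train on: no context pairs");
  total_pairs *= epochs;

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(-0.5, 0.5);
  std::uniform_int_distribution<int> draw_term(0, vocab_size - 1);

  std::vector<double> emb(static_cast<size_t>(vocab_size) * dim);
  for (auto &e : emb) e = unif(rng) / dim;

  std::vector<double> grad_w(dim);
  long long done = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < n_seq; ++i) {
      const std::vector<int> &s = seqs[i];
      const int n = s.size();
      for (int pos = 0; pos < n; ++pos) {
        const int w = s[pos];
        double *vw = &emb[static_cast<size_t>(w) * dim];
        int lo = std::max(0, pos - context), hi = std::min(n - 1, pos + context);
        for (int j = lo; j <= hi; ++j) {
          if (j == pos) continue;
          double lr = alpha * (1.0 - static_cast<double>(done) / total_pairs);
          if (lr < alpha_min) lr = alpha_min;
          ++done;
          const int c = s[j];
          double *vc = &emb[static_cast<size_t>(c) * dim];
          std::fill(grad_w.begin(), grad_w.end(), 0.0);
          // positive pair: ascend log sigmoid(vw . vc)
          double dot = 0.0;
          for (int k = 0; k < dim; ++k) dot += vw[k] * vc[k];
          double g = 1.0 - sigmoid(dot);
          for (int k = 0; k < dim; ++k) {
            grad_w[k] += g * vc[k];
            vc[k] += lr * g * vw[k];
          }
          // negatives: uniform over the whole vocabulary (the center itself
          // may be drawn; its -sigmoid(|vw|^2) term is what keeps vector
          // norms bounded with a single shared table)
          for (int m = 0; m < negative; ++m) {
            int u = draw_term(rng);
            double *vu = &emb[static_cast<size_t>(u) * dim];
            double dotu = 0.0;
            for (int k = 0; k < dim; ++k) dotu += vw[k] * vu[k];
            double gu = -sigmoid(dotu);
            for (int k = 0; k < dim; ++k) {
              grad_w[k] += gu * vu[k];
              vu[k] += lr * gu * vw[k];
            }
          }
          for (int k = 0; k < dim; ++k) vw[k] += lr * grad_w[k];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int k = 0; k < dim; ++k)
      out(v, k) = emb[static_cast<size_t>(v) * dim + k];
  return out;
}

// The uniform negative-term generator used by the trainer, exposed so its
// distribution can be tested directly. Returns 1-based term indices.
// [[Rcpp::export]]
IntegerVector sgns_draw_negatives_cpp(int n, int vocab_size, int seed) {
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_int_distribution<int> draw_term(0, vocab_size - 1);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = draw_term(rng) + 1;
  return out;
}
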