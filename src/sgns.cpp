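// Skip-gram word-embedding trainer with negative sampling.
// Single-threaded with an internal xorshift RNG so that training is
// bit-reproducible given the seed. Follows the classical formulation:
// dynamic context window, unigram^0.75 negative-sampling table, linearly
// decaying learning rate, sigmoid lookup table.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

const int EXP_TABLE_SIZE = 1000;
const double MAX_EXP = 6.0;

struct XorShift {
  unsigned long long s;
  explicit XorShift(unsigned long long seed) : s(seed ? seed : 88172645463325252ULL) {}
  unsigned long long next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  // uniform integer in [0, n)
  unsigned long long next_int(unsigned long long n) { return next() % n; }
  double next_unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

}  // namespace

// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List docs, int vocab_size, NumericVector counts,
                         int dim, int window, int negative, int epochs,
                         double alpha, int seed) {
  // negative-sampling table over the unigram distribution ^ 0.75
  const int table_size = 1000000;
  std::vector<int> table(table_size);
  {
    double z = 0.0;
    for (int i = 0; i < vocab_size; ++i) z += std::pow(counts[i], 0.75);
    double cum = std::pow(counts[0], 0.75) / z;
    int w = 0;
    for (int i = 0; i < table_size; ++i) {
      table[i] = w;
      if ((double)i / table_size > cum && w < vocab_size - 1) {
        ++w;
        cum += std::pow(counts[w], 0.75) / z;
      }
    }
  }

  std::vector<double> expTable(EXP_TABLE_SIZE);
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    double x = std::exp(((double)i / EXP_TABLE_SIZE * 2.0 - 1.0) * MAX_EXP);
    expTable[i] = x / (x + 1.0);
  }

  XorShift rng((unsigned long long)seed * 2654435761ULL + 1ULL);

  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.next_unif() - 0.5) / dim;

  long long total_tokens = 0;
  int n_docs = docs.size();
  std::vector<std::vector<int>> sents(n_docs);
  for (int d = 0; d < n_docs; ++d) {
    IntegerVector v = docs[d];
    sents[d].assign(v.begin(), v.end());
    total_tokens += v.size();
  }
  long long train_total = total_tokens * (long long)epochs;
  long long processed = 0;

  std::vector<double> neu1e(dim);
  double lr = alpha;
  const double min_lr = alpha * 1e-4;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < n_docs; ++d) {
      const std::vector<int> &sent = sents[d];
      int len = (int)sent.size();
      for (int pos = 0; pos < len; ++pos) {
        lr = alpha * (1.0 - (double)processed / (double)(train_total + 1));
        if (lr < min_lr) lr = min_lr;
        ++processed;
        int word = sent[pos];  // center (predicted) word
        int b = (int)rng.next_int((unsigned long long)window);
        for (int a = b; a < window * 2 + 1 - b; ++a) {
          if (a == window) continue;
          int c = pos - window + a;
          if (c < 0 || c >= len) continue;
          int last_word = sent[c];  // context (input) word
          double *l1 = &syn0[(size_t)last_word * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int n = 0; n <= negative; ++n) {
            int target; double label;
            if (n == 0) { target = word; label = 1.0; }
            else {
              target = table[rng.next_int(table_size)];
              if (target == word) continue;
              label = 0.0;
            }
            double *l2 = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int i = 0; i < dim; ++i) f += l1[i] * l2[i];
            double g;
            if (f > MAX_EXP) g = (label - 1.0) * lr;
            else if (f < -MAX_EXP) g = label * lr;
            else {
              int idx = (int)((f + MAX_EXP) * (EXP_TABLE_SIZE / MAX_EXP / 2.0));
              g = (label - expTable[idx]) * lr;
            }
            for (int i = 0; i < dim; ++i) neu1e[i] += g * l2[i];
            for (int i = 0; i < dim; ++i) l2[i] += g * l1[i];
          }
          for (int i = 0; i < dim; ++i) l1[i] += neu1e[i];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int w = 0; w < vocab_size; ++w)
    for (int i = 0; i < dim; ++i)
      out(w, i) = syn0[(size_t)w * dim + i];
  return out;
}
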