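// Skip-gram with negative sampling (code-level embeddings) and distributed
// bag-of-words (window-level embeddings), single-threaded and fully
// deterministic given a seed. Token indices are 1-based (R convention);
// sequences passed here contain in-vocabulary tokens only.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

uint64_t fnv_hash(const int* v, int n) {
  uint64_t h = 1469598103934665603ULL;
  for (int i = 0; i < n; ++i) {
    h ^= static_cast<uint64_t>(v[i]) + 0x9E37;
    h *= 1099511628211ULL;
  }
  return h;
}

std::vector<double> neg_cdf(const IntegerVector& counts) {
  std::vector<double> cdf(counts.size());
  double acc = 0.0;
  for (int i = 0; i < counts.size(); ++i) {
    acc += std::pow(static_cast<double>(counts[i]), 0.75);
    cdf[i] = acc;
  }
  for (size_t i = 0; i < cdf.size(); ++i) cdf[i] /= acc;
  return cdf;
}

// returns a 1-based token index sampled from the unigram^0.75 distribution
int sample_neg(const std::vector<double>& cdf, Rng& rng) {
  double u = rng.unif();
  return static_cast<int>(std::lower_bound(cdf.begin(), cdf.end(), u) -
                          cdf.begin()) + 1;
}

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// one negative-sampling update of an input vector `in` against target rows of
// `out`; returns via neu1e the accumulated input gradient
void ns_update(double* in, std::vector<double>& out, int dim, int target1b,
               int negative, const std::vector<double>& cdf, Rng& rng,
               double alpha, std::vector<double>& neu1e,
               bool update_out = true) {
  std::fill(neu1e.begin(), neu1e.end(), 0.0);
  for (int k = 0; k <= negative; ++k) {
    int tgt;
    double label;
    if (k == 0) {
      tgt = target1b;
      label = 1.0;
    } else {
      tgt = sample_neg(cdf, rng);
      if (tgt == target1b) continue;
      label = 0.0;
    }
    double* orow = &out[(tgt - 1) * static_cast<size_t>(dim)];
    double f = 0.0;
    for (int d = 0; d < dim; ++d) f += in[d] * orow[d];
    double g = (label - sigmoid(f)) * alpha;
    for (int d = 0; d < dim; ++d) neu1e[d] += g * orow[d];
    if (update_out) {
      for (int d = 0; d < dim; ++d) orow[d] += g * in[d];
    }
  }
  for (int d = 0; d < dim; ++d) in[d] += neu1e[d];
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_sgns_train(List seqs, int vocab_size, int dim, int window,
                             int negative, int epochs, double lr,
                             IntegerVector counts, int seed) {
  Rng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  std::vector<double> syn0(static_cast<size_t>(vocab_size) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab_size) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) syn0[i] = (rng.unif() - 0.5) / dim;
  std::vector<double> cdf = neg_cdf(counts);
  std::vector<double> neu1e(dim);

  long long total_words = 0;
  for (int s = 0; s < seqs.size(); ++s) {
    total_words += Rf_length(seqs[s]);
  }
  total_words *= epochs;
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < seqs.size(); ++s) {
      IntegerVector seq = seqs[s];
      int T = seq.size();
      for (int i = 0; i < T; ++i) {
        ++processed;
        double alpha = lr * std::max(1e-4, 1.0 - static_cast<double>(processed) /
                                                 (total_words + 1.0));
        int b = rng.below(window); // dynamic window shrink, word2vec style
        for (int j = i - window + b; j <= i + window - b; ++j) {
          if (j == i || j < 0 || j >= T) continue;
          double* in = &syn0[(seq[i] - 1) * static_cast<size_t>(dim)];
          ns_update(in, syn1, dim, seq[j], negative, cdf, rng, alpha, neu1e);
        }
      }
    }
  }
  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v) {
    for (int d = 0; d < dim; ++d) out(v, d) = syn0[v * static_cast<size_t>(dim) + d];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_dbow_train(List seqs, int vocab_size, int dim, int negative,
                    int epochs, double lr, IntegerVector counts, int seed) {
  int n_docs = seqs.size();
  Rng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 7ULL);
  std::vector<double> docs(static_cast<size_t>(n_docs) * dim);
  std::vector<double> out(static_cast<size_t>(vocab_size) * dim, 0.0);
  for (size_t i = 0; i < docs.size(); ++i) docs[i] = (rng.unif() - 0.5) / dim;
  std::vector<double> cdf = neg_cdf(counts);
  std::vector<double> neu1e(dim);

  long long total_words = 0;
  for (int s = 0; s < n_docs; ++s) total_words += Rf_length(seqs[s]);
  total_words *= epochs;
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_docs; ++s) {
      IntegerVector seq = seqs[s];
      double* dv = &docs[s * static_cast<size_t>(dim)];
      for (int i = 0; i < seq.size(); ++i) {
        ++processed;
        double alpha = lr * std::max(1e-4, 1.0 - static_cast<double>(processed) /
                                                 (total_words + 1.0));
        ns_update(dv, out, dim, seq[i], negative, cdf, rng, alpha, neu1e);
      }
    }
  }
  NumericMatrix doc_mat(n_docs, dim), out_mat(vocab_size, dim);
  for (int s = 0; s < n_docs; ++s)
    for (int d = 0; d < dim; ++d) doc_mat(s, d) = docs[s * static_cast<size_t>(dim) + d];
  for (int v = 0; v < vocab_size; ++v)
    for (int d = 0; d < dim; ++d) out_mat(v, d) = out[v * static_cast<size_t>(dim) + d];
  return List::create(Named("doc") = doc_mat, Named("out") = out_mat);
}

// Infer vectors for unseen documents against a frozen output matrix. Each
// document's RNG stream is seeded from the (content hash of the) sequence,
// so inference is independent of batch composition and order.
// [[Rcpp::export]]
NumericMatrix cpp_dbow_infer(List seqs, NumericMatrix out_mat,
                             IntegerVector counts, int negative, int epochs,
                             double lr, int seed) {
  int n_docs = seqs.size();
  int dim = out_mat.ncol();
  int vocab_size = out_mat.nrow();
  std::vector<double> out(static_cast<size_t>(vocab_size) * dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int d = 0; d < dim; ++d) out[v * static_cast<size_t>(dim) + d] = out_mat(v, d);
  std::vector<double> cdf = neg_cdf(counts);
  std::vector<double> neu1e(dim);
  NumericMatrix res(n_docs, dim);

  for (int s = 0; s < n_docs; ++s) {
    IntegerVector seq = seqs[s];
    int T = seq.size();
    if (T == 0) continue; // zero vector for empty sequences
    Rng rng(fnv_hash(&seq[0], T) ^ (static_cast<uint64_t>(seed) * 0x9E3779B9ULL));
    std::vector<double> dv(dim);
    for (int d = 0; d < dim; ++d) dv[d] = (rng.unif() - 0.5) / dim;
    long long total = static_cast<long long>(T) * epochs;
    long long processed = 0;
    for (int ep = 0; ep < epochs; ++ep) {
      for (int i = 0; i < T; ++i) {
        ++processed;
        double alpha = lr * std::max(1e-4, 1.0 - static_cast<double>(processed) /
                                                 (total + 1.0));
        // output weights stay frozen during inference
        ns_update(dv.data(), out, dim, seq[i], negative, cdf, rng, alpha,
                  neu1e, false);
      }
    }
    for (int d = 0; d < dim; ++d) res(s, d) = dv[d];
  }
  return res;
}
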