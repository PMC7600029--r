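// Recurrent (LSTM) fracture-risk classifier: a single LSTM layer consumes
// the embedded code sequence; its final hidden state is concatenated with a
// dense (ReLU) transform of the static features (age, sex, diagnosis
// count), passed through a merge dense layer and a sigmoid head. Trained
// with binary cross-entropy and Adam, single-threaded, deterministic given
// the seed. Code embeddings are frozen (no gradient flows into them).

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

struct Dims {
  int D, H, S, Sh, M;
  size_t oW, oU, ob, oWs, obs, oWm, obm, owo, obo, total;
};

Dims make_dims(int D, int H, int S, int Sh, int M) {
  Dims d;
  d.D = D; d.H = H; d.S = S; d.Sh = Sh; d.M = M;
  size_t o = 0;
  d.oW = o;  o += static_cast<size_t>(4) * H * D;
  d.oU = o;  o += static_cast<size_t>(4) * H * H;
  d.ob = o;  o += static_cast<size_t>(4) * H;
  d.oWs = o; o += static_cast<size_t>(Sh) * S;
  d.obs = o; o += Sh;
  d.oWm = o; o += static_cast<size_t>(M) * (H + Sh);
  d.obm = o; o += M;
  d.owo = o; o += M;
  d.obo = o; o += 1;
  d.total = o;
  return d;
}

inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// per-sample forward caches for backprop-through-time
struct Caches {
  std::vector<double> I, F, G, O, C, TC; // T x H each
  std::vector<double> H_all;             // (T+1) x H, row 0 = initial state
  std::vector<double> sh, m;             // post-ReLU dense activations
  double y;
};

void forward(const double* th, const Dims& d, const int* seq, int T,
             const double* embR, const double* stat, Caches& cc,
             bool keep = true) {
  int H = d.H, D = d.D;
  if (keep) {
    cc.I.assign(static_cast<size_t>(T) * H, 0.0);
    cc.F.assign(static_cast<size_t>(T) * H, 0.0);
    cc.G.assign(static_cast<size_t>(T) * H, 0.0);
    cc.O.assign(static_cast<size_t>(T) * H, 0.0);
    cc.C.assign(static_cast<size_t>(T) * H, 0.0);
    cc.TC.assign(static_cast<size_t>(T) * H, 0.0);
  }
  cc.H_all.assign(static_cast<size_t>(T + 1) * H, 0.0);
  std::vector<double> c(H, 0.0), z(4 * H);
  const double* W = th + d.oW;
  const double* U = th + d.oU;
  const double* b = th + d.ob;
  for (int t = 0; t < T; ++t) {
    const double* hprev = &cc.H_all[static_cast<size_t>(t) * H];
    const double* x = (seq[t] > 0) ? &embR[static_cast<size_t>(seq[t] - 1) * D]
                                   : nullptr;
    for (int j = 0; j < 4 * H; ++j) {
      double acc = b[j];
      if (x != nullptr) {
        const double* wrow = &W[static_cast<size_t>(j) * D];
        for (int k = 0; k < D; ++k) acc += wrow[k] * x[k];
      }
      const double* urow = &U[static_cast<size_t>(j) * H];
      for (int k = 0; k < H; ++k) acc += urow[k] * hprev[k];
      z[j] = acc;
    }
    double* hrow = &cc.H_all[static_cast<size_t>(t + 1) * H];
    for (int j = 0; j < H; ++j) {
      double iv = sigmoid(z[j]);
      double fv = sigmoid(z[H + j]);
      double gv = std::tanh(z[2 * H + j]);
      double ov = sigmoid(z[3 * H + j]);
      c[j] = fv * c[j] + iv * gv;
      double tc = std::tanh(c[j]);
      hrow[j] = ov * tc;
      if (keep) {
        size_t at = static_cast<size_t>(t) * H + j;
        cc.I[at] = iv; cc.F[at] = fv; cc.G[at] = gv; cc.O[at] = ov;
        cc.C[at] = c[j]; cc.TC[at] = tc;
      }
    }
  }
  // statics branch
  cc.sh.assign(d.Sh, 0.0);
  const double* Ws = th + d.oWs;
  const double* bs = th + d.obs;
  for (int j = 0; j < d.Sh; ++j) {
    double acc = bs[j];
    for (int k = 0; k < d.S; ++k) acc += Ws[static_cast<size_t>(j) * d.S + k] * stat[k];
    cc.sh[j] = acc > 0 ? acc : 0.0;
  }
  // merge layer over [h_T ; sh]
  cc.m.assign(d.M, 0.0);
  const double* Wm = th + d.oWm;
  const double* bm = th + d.obm;
  const double* hT = &cc.H_all[static_cast<size_t>(T) * H];
  int HS = H + d.Sh;
  for (int j = 0; j < d.M; ++j) {
    double acc = bm[j];
    const double* wrow = &Wm[static_cast<size_t>(j) * HS];
    for (int k = 0; k < H; ++k) acc += wrow[k] * hT[k];
    for (int k = 0; k < d.Sh; ++k) acc += wrow[H + k] * cc.sh[k];
    cc.m[j] = acc > 0 ? acc : 0.0;
  }
  const double* wo = th + d.owo;
  double acc = th[d.obo];
  for (int j = 0; j < d.M; ++j) acc += wo[j] * cc.m[j];
  cc.y = sigmoid(acc);
}

// accumulate gradient of BCE loss for one sample into g
void backward(const double* th, const Dims& d, const int* seq, int T,
              const double* embR, const double* stat, double label,
              const Caches& cc, double* g) {
  int H = d.H, D = d.D, Sh = d.Sh, M = d.M, S = d.S;
  int HS = H + Sh;
  double dy = cc.y - label; // d loss / d pre-sigmoid output
  const double* wo = th + d.owo;
  const double* Wm = th + d.oWm;
  const double* U = th + d.oU;
  const double* Ws = th + d.oWs;
  const double* hT = &cc.H_all[static_cast<size_t>(T) * H];

  std::vector<double> dm(M), dhT(H, 0.0), dsh(Sh, 0.0);
  for (int j = 0; j < M; ++j) {
    g[d.owo + j] += dy * cc.m[j];
    dm[j] = (cc.m[j] > 0.0) ? dy * wo[j] : 0.0;
  }
  g[d.obo] += dy;
  for (int j = 0; j < M; ++j) {
    if (dm[j] == 0.0) continue;
    const double* wrow = &Wm[static_cast<size_t>(j) * HS];
    double* grow = &g[d.oWm + static_cast<size_t>(j) * HS];
    for (int k = 0; k < H; ++k) {
      grow[k] += dm[j] * hT[k];
      dhT[k] += dm[j] * wrow[k];
    }
    for (int k = 0; k < Sh; ++k) {
      grow[H + k] += dm[j] * cc.sh[k];
      dsh[k] += dm[j] * wrow[H + k];
    }
    g[d.obm + j] += dm[j];
  }
  for (int j = 0; j < Sh; ++j) {
    if (cc.sh[j] <= 0.0) continue;
    for (int k = 0; k < S; ++k) g[d.oWs + static_cast<size_t>(j) * S + k] += dsh[j] * stat[k];
    g[d.obs + j] += dsh[j];
  }
  (void)Ws;

  // backprop through time
  std::vector<double> dh(dhT), dc(H, 0.0), dz(4 * H);
  for (int t = T - 1; t >= 0; --t) {
    const double* hprev = &cc.H_all[static_cast<size_t>(t) * H];
    const double* x = (seq[t] > 0) ? &embR[static_cast<size_t>(seq[t] - 1) * D]
                                   : nullptr;
    for (int j = 0; j < H; ++j) {
      size_t at = static_cast<size_t>(t) * H + j;
      double iv = cc.I[at], fv = cc.F[at], gv = cc.G[at], ov = cc.O[at];
      double tc = cc.TC[at];
      double dcj = dc[j] + dh[j] * ov * (1.0 - tc * tc);
      double cprev = (t > 0) ? cc.C[at - H] : 0.0;
      dz[j] = dcj * gv * iv * (1.0 - iv);                   // input gate
      dz[H + j] = dcj * cprev * fv * (1.0 - fv);            // forget gate
      dz[2 * H + j] = dcj * iv * (1.0 - gv * gv);           // candidate
      dz[3 * H + j] = dh[j] * tc * ov * (1.0 - ov);         // output gate
      dc[j] = dcj * fv;
    }
    std::fill(dh.begin(), dh.end(), 0.0);
    for (int j = 0; j < 4 * H; ++j) {
      double dzj = dz[j];
      if (dzj == 0.0) continue;
      if (x != nullptr) {
        double* grow = &g[d.oW + static_cast<size_t>(j) * D];
        for (int k = 0; k < D; ++k) grow[k] += dzj * x[k];
      }
      double* gurow = &g[d.oU + static_cast<size_t>(j) * H];
      const double* urow = &U[static_cast<size_t>(j) * H];
      for (int k = 0; k < H; ++k) {
        gurow[k] += dzj * hprev[k];
        dh[k] += dzj * urow[k];
      }
      g[d.ob + j] += dzj;
    }
  }
}

double rank_auc(const std::vector<double>& p, const std::vector<int>& y) {
  int n = p.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) { return p[a] < p[b]; });
  std::vector<double> r(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && p[idx[j + 1]] == p[idx[i]]) ++j;
    double avg = (i + j) / 2.0 + 1.0;
    for (int k = i; k <= j; ++k) r[idx[k]] = avg;
    i = j + 1;
  }
  double sum_pos = 0.0;
  long long npos = 0;
  for (int k = 0; k < n; ++k) {
    if (y[k] == 1) { sum_pos += r[k]; ++npos; }
  }
  long long nneg = n - npos;
  if (npos == 0 || nneg == 0) return 0.5;
  return (sum_pos - npos * (npos + 1) / 2.0) / (static_cast<double>(npos) * nneg);
}

std::vector<double> row_major(const NumericMatrix& m) {
  std::vector<double> out(static_cast<size_t>(m.nrow()) * m.ncol());
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < m.ncol(); ++j)
      out[static_cast<size_t>(i) * m.ncol() + j] = m(i, j);
  return out;
}

std::vector<double> predict_all(const double* th, const Dims& d,
                                const List& seqs, const double* embR,
                                const std::vector<double>& statR,
                                const std::vector<int>& which) {
  Caches cc;
  std::vector<double> out(which.size());
  for (size_t q = 0; q < which.size(); ++q) {
    int i = which[q];
    IntegerVector seq = seqs[i];
    forward(th, d, seq.size() ? &seq[0] : nullptr, seq.size(), embR,
            &statR[static_cast<size_t>(i) * d.S], cc, false);
    out[q] = cc.y;
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
List cpp_lstm_train(List seqs, NumericMatrix emb, NumericMatrix statics,
                    NumericVector labels, IntegerVector train_idx,
                    IntegerVector val_idx, int hidden, int dense_statics,
                    int dense_merge, int epochs, int batch, double lr,
                    int seed) {
  int D = emb.ncol();
  int S = statics.ncol();
  Dims d = make_dims(D, hidden, S, dense_statics, dense_merge);
  std::vector<double> embR = row_major(emb);
  std::vector<double> statR = row_major(statics);

  Rng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 13ULL);
  std::vector<double> th(d.total), grad(d.total, 0.0);
  std::vector<double> am(d.total, 0.0), av(d.total, 0.0); // Adam moments
  // Xavier-style init per block
  auto init_block = [&](size_t off, size_t n, int fan_in, int fan_out) {
    double r = std::sqrt(6.0 / (fan_in + fan_out));
    for (size_t i = 0; i < n; ++i) th[off + i] = (rng.unif() * 2.0 - 1.0) * r;
  };
  init_block(d.oW, static_cast<size_t>(4) * d.H * D, D, d.H);
  init_block(d.oU, static_cast<size_t>(4) * d.H * d.H, d.H, d.H);
  std::fill(th.begin() + d.ob, th.begin() + d.ob + 4 * d.H, 0.0);
  for (int j = 0; j < d.H; ++j) th[d.ob + d.H + j] = 1.0; // forget-gate bias
  init_block(d.oWs, static_cast<size_t>(d.Sh) * S, S, d.Sh);
  std::fill(th.begin() + d.obs, th.begin() + d.obs + d.Sh, 0.0);
  init_block(d.oWm, static_cast<size_t>(d.M) * (d.H + d.Sh), d.H + d.Sh, d.M);
  std::fill(th.begin() + d.obm, th.begin() + d.obm + d.M, 0.0);
  init_block(d.owo, d.M, d.M, 1);
  th[d.obo] = 0.0;

  std::vector<int> tr(train_idx.begin(), train_idx.end());
  for (size_t i = 0; i < tr.size(); ++i) tr[i] -= 1; // to 0-based
  std::vector<int> va(val_idx.begin(), val_idx.end());
  for (size_t i = 0; i < va.size(); ++i) va[i] -= 1;
  std::vector<int> va_y(va.size());
  for (size_t i = 0; i < va.size(); ++i) va_y[i] = labels[va[i]] >= 0.5 ? 1 : 0;

  double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long long step = 0;
  Caches cc;
  std::vector<double> best_th = th;
  double best_auc = -1.0;
  int best_epoch = 0;
  NumericVector val_history(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle of the training order
    for (int i = static_cast<int>(tr.size()) - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      std::swap(tr[i], tr[j]);
    }
    size_t pos = 0;
    while (pos < tr.size()) {
      size_t bend = std::min(pos + static_cast<size_t>(batch), tr.size());
      std::fill(grad.begin(), grad.end(), 0.0);
      for (size_t q = pos; q < bend; ++q) {
        int i = tr[q];
        IntegerVector seq = seqs[i];
        const int* sp = seq.size() ? &seq[0] : nullptr;
        forward(th.data(), d, sp, seq.size(), embR.data(),
                &statR[static_cast<size_t>(i) * S], cc, true);
        backward(th.data(), d, sp, seq.size(), embR.data(),
                 &statR[static_cast<size_t>(i) * S], labels[i], cc,
                 grad.data());
      }
      double inv = 1.0 / static_cast<double>(bend - pos);
      ++step;
      double bc1 = 1.0 - std::pow(beta1, static_cast<double>(step));
      double bc2 = 1.0 - std::pow(beta2, static_cast<double>(step));
      for (size_t k = 0; k < d.total; ++k) {
        double gk = grad[k] * inv;
        am[k] = beta1 * am[k] + (1.0 - beta1) * gk;
        av[k] = beta2 * av[k] + (1.0 - beta2) * gk * gk;
        th[k] -= lr * (am[k] / bc1) / (std::sqrt(av[k] / bc2) + eps);
      }
      pos = bend;
    }
    if (!va.empty()) {
      std::vector<double> vp = predict_all(th.data(), d, seqs, embR.data(),
                                           statR, va);
      double auc = rank_auc(vp, va_y);
      val_history[ep] = auc;
      if (auc > best_auc) {
        best_auc = auc;
        best_th = th;
        best_epoch = ep + 1;
      }
    } else {
      val_history[ep] = NA_REAL;
      best_th = th;
      best_epoch = ep + 1;
    }
  }

  return List::create(
      Named("theta") = NumericVector(best_th.begin(), best_th.end()),
      Named("dims") = IntegerVector::create(D, d.H, S, d.Sh, d.M),
      Named("val_auc") = val_history,
      Named("best_epoch") = best_epoch,
      Named("best_val_auc") = best_auc);
}

// [[Rcpp::export]]
NumericVector cpp_lstm_predict(NumericVector theta, IntegerVector dims,
                               List seqs, NumericMatrix emb,
                               NumericMatrix statics) {
  Dims d = make_dims(dims[0], dims[1], dims[2], dims[3], dims[4]);
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> embR = row_major(emb);
  std::vector<double> statR = row_major(statics);
  std::vector<int> all(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) all[i] = i;
  std::vector<double> p = predict_all(th.data(), d, seqs, embR.data(), statR,
                                      all);
  return NumericVector(p.begin(), p.end());
}
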