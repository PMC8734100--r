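// Compact transformer encoder language model with masked-span training.
//
// The model is non-directional: no causal mask is applied anywhere, every
// position attends to every position in its window.  Training replaces the
// tokens of contiguous spans by a reserved placeholder id (= vocab size) and
// predicts the original tokens at those positions from the full window.
// Pre-norm encoder blocks (LN -> MHA -> residual, LN -> FFN -> residual)
// with a final layer norm — the pre-norm arrangement keeps gradients well
// scaled from the first step, which matters in the few-epoch regime this
// package trains in.  Sinusoidal positional encodings, Adam with
// global-norm gradient clipping.  All randomness (shuffling order, span
// phases) is drawn on the R side and passed in, so this file is purely
// deterministic numerical code.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

namespace {

constexpr double LN_EPS = 1e-5;

struct Layer {
  mat Wq, Wk, Wv, Wo, W1, W2;
  vec g1, b1, g2, b2, bf1, bf2;
};

struct Model {
  mat Emb;   // (V+1) x d, last row = placeholder embedding
  mat Wout;  // d x V
  vec bout;  // V
  vec gF, bF;  // final layer norm
  std::vector<Layer> layers;
  int d = 0, h = 0, V = 0, span = 1, phases = 1;
};

struct LayerGrad {
  mat Wq, Wk, Wv, Wo, W1, W2;
  vec g1, b1, g2, b2, bf1, bf2;
};

struct Grad {
  mat Emb, Wout;
  vec bout, gF, bF;
  std::vector<LayerGrad> layers;
};

Model unpack(const List& params, const List& cfg) {
  Model m;
  m.d = as<int>(cfg["d_model"]);
  m.h = as<int>(cfg["n_heads"]);
  m.V = as<int>(cfg["n_tokens"]);
  m.span = as<int>(cfg["mask_span"]);
  m.phases = as<int>(cfg["mask_phases"]);
  m.Emb = as<mat>(params["Emb"]);
  m.Wout = as<mat>(params["Wout"]);
  m.bout = as<vec>(params["bout"]);
  m.gF = as<vec>(params["gF"]);
  m.bF = as<vec>(params["bF"]);
  List ls = params["layers"];
  for (int i = 0; i < ls.size(); ++i) {
    List l = ls[i];
    Layer L;
    L.Wq = as<mat>(l["Wq"]);  L.Wk = as<mat>(l["Wk"]);
    L.Wv = as<mat>(l["Wv"]);  L.Wo = as<mat>(l["Wo"]);
    L.W1 = as<mat>(l["W1"]);  L.W2 = as<mat>(l["W2"]);
    L.g1 = as<vec>(l["g1"]);  L.b1 = as<vec>(l["b1"]);
    L.g2 = as<vec>(l["g2"]);  L.b2 = as<vec>(l["b2"]);
    L.bf1 = as<vec>(l["bf1"]); L.bf2 = as<vec>(l["bf2"]);
    m.layers.push_back(std::move(L));
  }
  return m;
}

List pack(const Model& m) {
  List ls(m.layers.size());
  for (size_t i = 0; i < m.layers.size(); ++i) {
    const Layer& L = m.layers[i];
    ls[i] = List::create(
      _["Wq"] = L.Wq, _["Wk"] = L.Wk, _["Wv"] = L.Wv, _["Wo"] = L.Wo,
      _["W1"] = L.W1, _["W2"] = L.W2,
      _["g1"] = L.g1, _["b1"] = L.b1, _["g2"] = L.g2, _["b2"] = L.b2,
      _["bf1"] = L.bf1, _["bf2"] = L.bf2);
  }
  return List::create(_["Emb"] = m.Emb, _["Wout"] = m.Wout,
                      _["bout"] = m.bout, _["gF"] = m.gF, _["bF"] = m.bF,
                      _["layers"] = ls);
}

Grad zero_grad(const Model& m) {
  Grad g;
  g.Emb = zeros<mat>(size(m.Emb));
  g.Wout = zeros<mat>(size(m.Wout));
  g.bout = zeros<vec>(m.bout.n_elem);
  g.gF = zeros<vec>(m.gF.n_elem);
  g.bF = zeros<vec>(m.bF.n_elem);
  for (const Layer& L : m.layers) {
    LayerGrad lg;
    lg.Wq = zeros<mat>(size(L.Wq)); lg.Wk = zeros<mat>(size(L.Wk));
    lg.Wv = zeros<mat>(size(L.Wv)); lg.Wo = zeros<mat>(size(L.Wo));
    lg.W1 = zeros<mat>(size(L.W1)); lg.W2 = zeros<mat>(size(L.W2));
    lg.g1 = zeros<vec>(L.g1.n_elem); lg.b1 = zeros<vec>(L.b1.n_elem);
    lg.g2 = zeros<vec>(L.g2.n_elem); lg.b2 = zeros<vec>(L.b2.n_elem);
    lg.bf1 = zeros<vec>(L.bf1.n_elem); lg.bf2 = zeros<vec>(L.bf2.n_elem);
    g.layers.push_back(std::move(lg));
  }
  return g;
}

// visit every parameter/gradient pair in a fixed order
template <typename F>
void for_each_param(Model& m, Grad& g, F f) {
  f(m.Emb, g.Emb); f(m.Wout, g.Wout);
  for (size_t i = 0; i < m.layers.size(); ++i) {
    Layer& L = m.layers[i]; LayerGrad& G = g.layers[i];
    f(L.Wq, G.Wq); f(L.Wk, G.Wk); f(L.Wv, G.Wv); f(L.Wo, G.Wo);
    f(L.W1, G.W1); f(L.W2, G.W2);
  }
}

template <typename F>
void for_each_vec(Model& m, Grad& g, F f) {
  f(m.bout, g.bout); f(m.gF, g.gF); f(m.bF, g.bF);
  for (size_t i = 0; i < m.layers.size(); ++i) {
    Layer& L = m.layers[i]; LayerGrad& G = g.layers[i];
    f(L.g1, G.g1); f(L.b1, G.b1); f(L.g2, G.g2); f(L.b2, G.b2);
    f(L.bf1, G.bf1); f(L.bf2, G.bf2);
  }
}

mat sinusoidal_pe(int T, int d) {
  mat pe(T, d, fill::zeros);
  for (int pos = 0; pos < T; ++pos) {
    for (int i = 0; 2 * i < d; ++i) {
      double freq = std::pow(10000.0, 2.0 * i / d);
      pe(pos, 2 * i) = std::sin(pos / freq);
      if (2 * i + 1 < d) pe(pos, 2 * i + 1) = std::cos(pos / freq);
    }
  }
  return pe;
}

void softmax_rows_inplace(mat& S) {
  for (uword r = 0; r < S.n_rows; ++r) {
    rowvec row = S.row(r);
    row -= row.max();
    row = exp(row);
    S.row(r) = row / accu(row);
  }
}

// positions masked under canonical span geometry: ((p - phase) mod block) < span
std::vector<int> span_mask(int T, int phase, int span, int phases) {
  int block = span * phases;
  std::vector<int> out;
  for (int p = 0; p < T; ++p) {
    int r = ((p - phase) % block + block) % block;
    if (r < span) out.push_back(p);
  }
  if (out.empty() && T > 0) out.push_back(((phase % T) + T) % T);
  return out;
}

// per-row layer norm forward; stores xhat and istd for backward
void ln_forward(const mat& X, const vec& g, const vec& b,
                mat& Y, mat& xhat, vec& istd) {
  const uword N = X.n_rows, d = X.n_cols;
  Y.set_size(N, d); xhat.set_size(N, d); istd.set_size(N);
  for (uword r = 0; r < N; ++r) {
    double mu = mean(X.row(r));
    double va = accu(square(X.row(r) - mu)) / d;
    double is = 1.0 / std::sqrt(va + LN_EPS);
    istd(r) = is;
    xhat.row(r) = (X.row(r) - mu) * is;
    Y.row(r) = xhat.row(r) % g.t() + b.t();
  }
}

void ln_backward(const mat& dY, const mat& xhat, const vec& istd,
                 const vec& g, mat& dX, vec& dg, vec& db) {
  const uword N = dY.n_rows;
  dX.set_size(N, dY.n_cols);
  dg += sum(dY % xhat, 0).t();
  db += sum(dY, 0).t();
  for (uword r = 0; r < N; ++r) {
    rowvec dxh = dY.row(r) % g.t();
    double m1 = mean(dxh);
    double m2 = mean(dxh % xhat.row(r));
    dX.row(r) = istd(r) * (dxh - m1 - xhat.row(r) * m2);
  }
}

struct LayerCache {
  mat Xin;                 // layer input
  mat Y1, xhat1;  vec istd1;  // LN1 output and stats
  mat Q, K, Vv, O;         // attention tensors (projections of Y1)
  mat X1;                  // Xin + attention output
  mat Y2, xhat2;  vec istd2;  // LN2 output and stats
  mat H;                   // FFN hidden (post-relu)
  std::vector<std::vector<mat>> P;  // [seq][head] attention weights
};

struct BatchCache {
  std::vector<LayerCache> layers;
  mat xhatF; vec istdF;    // final layer norm stats
  mat YF;                  // final normalized representation
};

// Forward pass over a batch of sequences (concatenated rows).
void forward(const Model& m, const std::vector<std::vector<int>>& ids_in,
             const std::vector<std::vector<int>>& masked,
             BatchCache& cache, const mat& pe) {
  const int d = m.d, h = m.h, dk = d / h;
  const size_t B = ids_in.size();
  std::vector<uword> off(B + 1, 0);
  for (size_t b = 0; b < B; ++b) off[b + 1] = off[b] + ids_in[b].size();
  const uword N = off[B];
  const double sc = std::sqrt((double)d);

  mat X(N, d);
  for (size_t b = 0; b < B; ++b) {
    std::vector<bool> is_m(ids_in[b].size(), false);
    for (int p : masked[b]) is_m[p] = true;
    for (size_t t = 0; t < ids_in[b].size(); ++t) {
      int id = is_m[t] ? m.V : ids_in[b][t];
      X.row(off[b] + t) = m.Emb.row(id) * sc + pe.row(t);
    }
  }

  cache.layers.assign(m.layers.size(), LayerCache());
  for (size_t li = 0; li < m.layers.size(); ++li) {
    const Layer& L = m.layers[li];
    LayerCache& C = cache.layers[li];
    C.Xin = X;
    ln_forward(C.Xin, L.g1, L.b1, C.Y1, C.xhat1, C.istd1);
    C.Q = C.Y1 * L.Wq; C.K = C.Y1 * L.Wk; C.Vv = C.Y1 * L.Wv;
    C.O.set_size(N, d);
    C.P.assign(B, std::vector<mat>(h));
    for (size_t b = 0; b < B; ++b) {
      uword r0 = off[b], r1 = off[b + 1] - 1;
      for (int hh = 0; hh < h; ++hh) {
        uword c0 = hh * dk, c1 = (hh + 1) * dk - 1;
        mat S = C.Q.submat(r0, c0, r1, c1) *
                C.K.submat(r0, c0, r1, c1).t() / std::sqrt((double)dk);
        softmax_rows_inplace(S);
        C.P[b][hh] = S;
        C.O.submat(r0, c0, r1, c1) = S * C.Vv.submat(r0, c0, r1, c1);
      }
    }
    C.X1 = C.Xin + C.O * L.Wo;
    ln_forward(C.X1, L.g2, L.b2, C.Y2, C.xhat2, C.istd2);
    C.H = C.Y2 * L.W1;
    C.H.each_row() += L.bf1.t();
    C.H.transform([](double v) { return v > 0 ? v : 0.0; });
    mat F = C.H * L.W2;
    F.each_row() += L.bf2.t();
    X = C.X1 + F;
  }
  ln_forward(X, m.gF, m.bF, cache.YF, cache.xhatF, cache.istdF);
}

// loss (sum of -log p over masked positions) and optional gradients
double loss_and_backward(const Model& m,
                         const std::vector<std::vector<int>>& ids_in,
                         const std::vector<std::vector<int>>& masked,
                         Grad* grad, long& n_scored,
                         std::vector<vec>* probs_out = nullptr,
                         std::vector<double>* nats_per_seq = nullptr) {
  const size_t B = ids_in.size();
  int maxT = 0;
  for (auto& s : ids_in) maxT = std::max<int>(maxT, s.size());
  mat pe = sinusoidal_pe(maxT, m.d);

  BatchCache cache;
  forward(m, ids_in, masked, cache, pe);

  std::vector<uword> off(B + 1, 0);
  for (size_t b = 0; b < B; ++b) off[b + 1] = off[b] + ids_in[b].size();
  const uword N = off[B];

  double loss = 0.0;
  long nm = 0;
  for (auto& v : masked) nm += v.size();
  n_scored = nm;

  mat dYF(N, m.d, fill::zeros);
  if (nats_per_seq) nats_per_seq->assign(B, 0.0);
  for (size_t b = 0; b < B; ++b) {
    for (int p : masked[b]) {
      uword r = off[b] + p;
      rowvec logits = cache.YF.row(r) * m.Wout + m.bout.t();
      logits -= logits.max();
      rowvec ex = exp(logits);
      vec prob = (ex / accu(ex)).t();
      int y = ids_in[b][p];
      double nats = -std::log(std::max(prob(y), 1e-300));
      loss += nats;
      if (nats_per_seq) (*nats_per_seq)[b] += nats;
      if (probs_out) probs_out->push_back(prob);
      if (grad) {
        vec dlogit = prob;
        dlogit(y) -= 1.0;
        dlogit /= (double)nm;  // mean loss over masked positions
        grad->Wout += cache.YF.row(r).t() * dlogit.t();
        grad->bout += dlogit;
        dYF.row(r) = dlogit.t() * m.Wout.t();
      }
    }
  }
  if (!grad) return loss;

  const int d = m.d, h = m.h, dk = d / h;
  mat dX;
  ln_backward(dYF, cache.xhatF, cache.istdF, m.gF, dX, grad->gF, grad->bF);
  for (int li = (int)m.layers.size() - 1; li >= 0; --li) {
    const Layer& L = m.layers[li];
    LayerCache& C = cache.layers[li];
    LayerGrad& G = grad->layers[li];

    // FFN branch: Xout = X1 + relu(Y2 W1 + bf1) W2 + bf2
    mat dX1 = dX;  // residual
    mat dH = dX * L.W2.t();
    G.W2 += C.H.t() * dX;
    G.bf2 += sum(dX, 0).t();
    mat relu_mask = conv_to<mat>::from(C.H > 0);
    mat dpre = dH % relu_mask;
    G.W1 += C.Y2.t() * dpre;
    G.bf1 += sum(dpre, 0).t();
    mat dY2 = dpre * L.W1.t();
    mat dX1_ln;
    ln_backward(dY2, C.xhat2, C.istd2, L.g2, dX1_ln, G.g2, G.b2);
    dX1 += dX1_ln;

    // attention branch: X1 = Xin + MHA(Y1) Wo
    mat dXin = dX1;  // residual
    mat dA = dX1;
    mat dO = dA * L.Wo.t();
    G.Wo += C.O.t() * dA;
    mat dQ(size(C.Q), fill::zeros), dK(size(C.K), fill::zeros),
        dV(size(C.Vv), fill::zeros);
    for (size_t b = 0; b < B; ++b) {
      uword r0 = off[b], r1 = off[b + 1] - 1;
      for (int hh = 0; hh < h; ++hh) {
        uword c0 = hh * dk, c1 = (hh + 1) * dk - 1;
        const mat& P = C.P[b][hh];
        mat dOh = dO.submat(r0, c0, r1, c1);
        mat dP = dOh * C.Vv.submat(r0, c0, r1, c1).t();
        dV.submat(r0, c0, r1, c1) = P.t() * dOh;
        vec rs = sum(dP % P, 1);
        dP.each_col() -= rs;
        mat dS = P % dP;
        dS /= std::sqrt((double)dk);
        dQ.submat(r0, c0, r1, c1) = dS * C.K.submat(r0, c0, r1, c1);
        dK.submat(r0, c0, r1, c1) = dS.t() * C.Q.submat(r0, c0, r1, c1);
      }
    }
    G.Wq += C.Y1.t() * dQ;
    G.Wk += C.Y1.t() * dK;
    G.Wv += C.Y1.t() * dV;
    mat dY1 = dQ * L.Wq.t() + dK * L.Wk.t() + dV * L.Wv.t();
    mat dXin_ln;
    ln_backward(dY1, C.xhat1, C.istd1, L.g1, dXin_ln, G.g1, G.b1);
    dXin += dXin_ln;
    dX = dXin;
  }
  // embedding gradients
  const double sc = std::sqrt((double)d);
  for (size_t b = 0; b < B; ++b) {
    std::vector<bool> is_m(ids_in[b].size(), false);
    for (int p : masked[b]) is_m[p] = true;
    for (size_t t = 0; t < ids_in[b].size(); ++t) {
      int id = is_m[t] ? m.V : ids_in[b][t];
      grad->Emb.row(id) += dX.row(off[b] + t) * sc;
    }
  }
  return loss;
}

std::vector<std::vector<int>> as_seqs(const List& seqs) {
  std::vector<std::vector<int>> out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    IntegerVector v = seqs[i];
    out[i].assign(v.begin(), v.end());
  }
  return out;
}

struct Adam {
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  std::vector<mat> mM, vM;
  std::vector<vec> mV, vV;
  void init(Model& m, Grad& g) {
    for_each_param(m, g, [&](mat& p, mat&) {
      mM.push_back(zeros<mat>(size(p)));
      vM.push_back(zeros<mat>(size(p)));
    });
    for_each_vec(m, g, [&](vec& p, vec&) {
      mV.push_back(zeros<vec>(p.n_elem));
      vV.push_back(zeros<vec>(p.n_elem));
    });
  }
  void step(Model& m, Grad& g, double clip) {
    double nrm2 = 0.0;
    for_each_param(m, g, [&](mat&, mat& gr) { nrm2 += accu(square(gr)); });
    for_each_vec(m, g, [&](vec&, vec& gr) { nrm2 += accu(square(gr)); });
    double nrm = std::sqrt(nrm2);
    double scl = (clip > 0 && nrm > clip) ? clip / nrm : 1.0;
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    size_t i = 0;
    for_each_param(m, g, [&](mat& p, mat& gr) {
      mat gg = gr * scl;
      mM[i] = b1 * mM[i] + (1 - b1) * gg;
      vM[i] = b2 * vM[i] + (1 - b2) * square(gg);
      p -= lr * (mM[i] / c1) / (sqrt(vM[i] / c2) + eps);
      ++i;
    });
    size_t j = 0;
    for_each_vec(m, g, [&](vec& p, vec& gr) {
      vec gg = gr * scl;
      mV[j] = b1 * mV[j] + (1 - b1) * gg;
      vV[j] = b2 * vV[j] + (1 - b2) * square(gg);
      p -= lr * (mV[j] / c1) / (sqrt(vV[j] / c2) + eps);
      ++j;
    });
  }
};

}  // namespace

// [[Rcpp::export]]
arma::mat cpp_sinusoidal_pe(int T, int d_model) {
  return sinusoidal_pe(T, d_model);
}

// [[Rcpp::export]]
List cpp_transformer_train(List seqs, List params, List cfg, int epochs,
                           double lr, int batch_size, double clip,
                           IntegerMatrix phases, IntegerMatrix order) {
  Model m = unpack(params, cfg);
  auto S = as_seqs(seqs);
  const int n = S.size();
  if (n == 0) stop("empty corpus: nothing to train on");
  Grad g = zero_grad(m);
  Adam opt; opt.lr = lr; opt.init(m, g);
  NumericVector epoch_loss(epochs);
  for (int e = 0; e < epochs; ++e) {
    double tot = 0.0; long ntok = 0;
    for (int s0 = 0; s0 < n; s0 += batch_size) {
      int s1 = std::min(n, s0 + batch_size);
      std::vector<std::vector<int>> ids, mk;
      for (int i = s0; i < s1; ++i) {
        int idx = order(i, e);
        ids.push_back(S[idx]);
        mk.push_back(span_mask((int)S[idx].size(), phases(idx, e),
                               m.span, m.phases));
      }
      Grad gb = zero_grad(m);
      long nm = 0;
      double l = loss_and_backward(m, ids, mk, &gb, nm);
      if (!std::isfinite(l))
        stop("non-finite training loss at epoch %d", e + 1);
      tot += l; ntok += nm;
      opt.step(m, gb, clip);
    }
    epoch_loss[e] = tot / std::max<long>(ntok, 1);
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = pack(m), _["epoch_loss"] = epoch_loss);
}

// Score sequences: per-sequence total -log p (nats) and token counts.
// phases[i] >= 0: score only positions in that span phase of sequence i;
// phases[i] == -1: score every position exactly once (all canonical phases).
// [[Rcpp::export]]
List cpp_transformer_score(List seqs, List params, List cfg,
                           IntegerVector phases, int batch_size) {
  Model m = unpack(params, cfg);
  auto S = as_seqs(seqs);
  const int n = S.size();
  NumericVector nats(n);
  IntegerVector ntok(n);
  std::vector<std::pair<int, int>> items;
  for (int i = 0; i < n; ++i) {
    if (phases[i] >= 0) items.push_back({i, phases[i]});
    else for (int c = 0; c < m.phases; ++c) items.push_back({i, c * m.span});
  }
  for (size_t s0 = 0; s0 < items.size(); s0 += batch_size) {
    size_t s1 = std::min(items.size(), s0 + (size_t)batch_size);
    std::vector<std::vector<int>> ids, mk;
    for (size_t i = s0; i < s1; ++i) {
      ids.push_back(S[items[i].first]);
      mk.push_back(span_mask((int)S[items[i].first].size(), items[i].second,
                             m.span, m.phases));
    }
    long nm = 0;
    std::vector<double> per_seq;
    loss_and_backward(m, ids, mk, nullptr, nm, nullptr, &per_seq);
    for (size_t i = s0; i < s1; ++i) {
      nats[items[i].first] += per_seq[i - s0];
      ntok[items[i].first] += (int)mk[i - s0].size();
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["nats"] = nats, _["ntok"] = ntok);
}

// Predictive distributions at explicitly masked positions of one sequence.
// [[Rcpp::export]]
NumericMatrix cpp_transformer_probs(IntegerVector seq, List params, List cfg,
                                    IntegerVector masked) {
  Model m = unpack(params, cfg);
  std::vector<std::vector<int>> ids(1), mk(1);
  ids[0].assign(seq.begin(), seq.end());
  mk[0].assign(masked.begin(), masked.end());
  long nm = 0;
  std::vector<vec> probs;
  loss_and_backward(m, ids, mk, nullptr, nm, &probs);
  NumericMatrix out((int)probs.size(), m.V);
  for (size_t i = 0; i < probs.size(); ++i)
    for (int j = 0; j < m.V; ++j) out(i, j) = probs[i](j);
  return out;
}

// Loss and analytic gradients for one explicit batch; used by the
// finite-difference gradient checks.
// [[Rcpp::export]]
List cpp_transformer_loss_grads(List seqs, List masked, List params, List cfg) {
  Model m = unpack(params, cfg);
  auto S = as_seqs(seqs);
  std::vector<std::vector<int>> mk(masked.size());
  for (int i = 0; i < masked.size(); ++i) {
    IntegerVector v = masked[i];
    mk[i].assign(v.begin(), v.end());
  }
  Grad g = zero_grad(m);
  long nm = 0;
  double loss = loss_and_backward(m, S, mk, &g, nm);
  double mean_loss = loss / std::max<long>(nm, 1);
  Model gm;
  gm.Emb = g.Emb; gm.Wout = g.Wout; gm.bout = g.bout;
  gm.gF = g.gF; gm.bF = g.bF;
  for (auto& lg : g.layers) {
    Layer L;
    L.Wq = lg.Wq; L.Wk = lg.Wk; L.Wv = lg.Wv; L.Wo = lg.Wo;
    L.W1 = lg.W1; L.W2 = lg.W2;
    L.g1 = lg.g1; L.b1 = lg.b1; L.g2 = lg.g2; L.b2 = lg.b2;
    L.bf1 = lg.bf1; L.bf2 = lg.bf2;
    gm.layers.push_back(std::move(L));
  }
  return List::create(_["loss"] = mean_loss, _["grads"] = pack(gm),
                      _["n_masked"] = (double)nm);
}
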