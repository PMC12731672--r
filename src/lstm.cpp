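// Stacked-LSTM sequence classifier: forward pass, backpropagation through
// time, and the mini-batch training loop (Adam or plain SGD) used by the
// client side of the federated simulation.
//
// Conventions:
//  * Each record is a length-T sequence of scalars (T = number of input
//    columns); a batch of m records at step t is a (d x m) matrix.
//  * Each LSTM layer holds W (4h x d), U (4h x h), b (4h), with gate rows
//    stacked input/forget/candidate/output. Single-bias parameterization.
//  * The recurrent state uses the standard cell (sigmoid/tanh gates); a
//    ReLU is applied to the *emitted* output of every layer, followed by
//    inverted dropout during training. The last layer emits only its
//    final-step output, which feeds a dense softmax head.
//  * All randomness (shuffling, dropout masks) comes from R's RNG so that
//    seeding on the R side makes training fully deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

struct LstmLayer {
  mat W, U;
  vec b;
  int h, d;
};

struct Net {
  std::vector<LstmLayer> layers;
  mat Wd;
  vec bd;
  int n_classes;
};

static Net parse_net(const List& params, int n_classes) {
  Net net;
  int n_layers = (params.size() - 2) / 3;
  for (int l = 0; l < n_layers; ++l) {
    LstmLayer layer;
    layer.W = as<mat>(params[3 * l]);
    layer.U = as<mat>(params[3 * l + 1]);
    layer.b = vec(as<mat>(params[3 * l + 2]).col(0));
    layer.h = layer.U.n_cols;  // U is 4h x h
    layer.d = layer.W.n_cols;
    net.layers.push_back(layer);
  }
  net.Wd = as<mat>(params[params.size() - 2]);
  net.bd = vec(as<mat>(params[params.size() - 1]).col(0));
  net.n_classes = n_classes;
  return net;
}

static List net_to_list(const Net& net) {
  List out(3 * net.layers.size() + 2);
  for (size_t l = 0; l < net.layers.size(); ++l) {
    out[3 * l] = net.layers[l].W;
    out[3 * l + 1] = net.layers[l].U;
    out[3 * l + 2] = mat(net.layers[l].b);
    }
  out[out.size() - 2] = net.Wd;
  out[out.size() - 1] = mat(net.bd);
  return out;
}

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// Per-layer, per-batch caches needed by BPTT.
struct LayerCache {
  std::vector<mat> Xin;   // input at each step (d x m)
  std::vector<mat> I, F, G, O;  // gate activations (h x m)
  std::vector<mat> C, TC;       // cell state and tanh(C) (h x m)
  std::vector<mat> Hraw;        // pre-ReLU hidden output (h x m)
  std::vector<mat> Mask;        // combined ReLU+dropout multiplier (h x m)
  std::vector<mat> Emit;        // emitted output after ReLU+dropout
};

// Draw an inverted-dropout multiplier matrix from R's RNG.
static mat dropout_mask(int r, int c, double p) {
  mat m(r, c);
  double keep_scale = 1.0 / (1.0 - p);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i)
      m(i, j) = (unif_rand() >= p) ? keep_scale : 0.0;
  return m;
}

// Forward pass over a batch X (m x T). When `training` is true dropout
// masks are sampled; when `cache` is non-null everything needed for the
// backward pass is stored. Returns the dense-head input (h_last x m).
static mat forward(const Net& net, const mat& X, double dropout,
                   bool training, std::vector<LayerCache>* cache) {
  int T = X.n_cols;
  int m = X.n_rows;
  int L = net.layers.size();
  if (cache) cache->assign(L, LayerCache());

  // inputs to the current layer at each step, starting with the raw scalars
  std::vector<mat> inputs(T);
  for (int t = 0; t < T; ++t) inputs[t] = X.col(t).t();  // 1 x m

  mat last_emit;
  for (int l = 0; l < L; ++l) {
    const LstmLayer& ly = net.layers[l];
    bool emit_all = (l < L - 1);  // last layer emits only its final step
    mat H(ly.h, m, arma::fill::zeros);
    mat C(ly.h, m, arma::fill::zeros);
    LayerCache* lc = cache ? &((*cache)[l]) : nullptr;
    if (lc) {
      lc->Xin.resize(T); lc->I.resize(T); lc->F.resize(T); lc->G.resize(T);
      lc->O.resize(T); lc->C.resize(T); lc->TC.resize(T);
      lc->Hraw.resize(T); lc->Mask.resize(T); lc->Emit.resize(T);
    }
    std::vector<mat> emitted(emit_all ? T : 1);
    for (int t = 0; t < T; ++t) {
      const mat& xt = inputs[t];
      mat Z = ly.W * xt + ly.U * H;
      Z.each_col() += ly.b;
      mat I = sigmoid(Z.rows(0, ly.h - 1));
      mat F = sigmoid(Z.rows(ly.h, 2 * ly.h - 1));
      mat G = arma::tanh(Z.rows(2 * ly.h, 3 * ly.h - 1));
      mat O = sigmoid(Z.rows(3 * ly.h, 4 * ly.h - 1));
      mat Cnew = F % C + I % G;
      mat TC = arma::tanh(Cnew);
      mat Hraw = O % TC;
      if (lc) {
        lc->Xin[t] = xt; lc->I[t] = I; lc->F[t] = F; lc->G[t] = G;
        lc->O[t] = O; lc->C[t] = Cnew; lc->TC[t] = TC; lc->Hraw[t] = Hraw;
      }
      if (emit_all || t == T - 1) {
        mat relu_grad = arma::conv_to<mat>::from(Hraw > 0.0);
        mat mult = relu_grad;
        if (training && dropout > 0.0) mult %= dropout_mask(ly.h, m, dropout);
        mat E = mult % Hraw;  // equals dropout(relu(Hraw))
        if (lc) { lc->Mask[t] = mult; lc->Emit[t] = E; }
        if (emit_all) emitted[t] = E; else last_emit = E;
      }
      H = Hraw;  // recurrence carries the raw (pre-ReLU) hidden state
      C = Cnew;
    }
    if (emit_all) inputs = emitted;
  }
  return last_emit;  // h_last x m
}

static mat softmax_cols(const mat& logits) {
  mat z = logits.each_row() - arma::max(logits, 0);
  mat e = arma::exp(z);
  return e.each_row() / arma::sum(e, 0);
}

// Backward pass; fills `grad` (same shapes as net) and returns nothing.
// dA is the gradient w.r.t. the dense-head input (h_last x m).
static void backward(const Net& net, const std::vector<LayerCache>& cache,
                     const mat& dA_last, Net& grad) {
  int L = net.layers.size();
  int T = cache[0].Xin.size();
  int m = dA_last.n_cols;

  // gradient w.r.t. each layer's emitted outputs
  std::vector<mat> dEmit(T);
  for (int l = L - 1; l >= 0; --l) {
    const LstmLayer& ly = net.layers[l];
    const LayerCache& lc = cache[l];
    bool emit_all = (l < L - 1);
    mat dH_rec(ly.h, m, arma::fill::zeros);
    mat dC_rec(ly.h, m, arma::fill::zeros);
    mat gW(arma::size(ly.W), arma::fill::zeros);
    mat gU(arma::size(ly.U), arma::fill::zeros);
    vec gb(ly.b.n_elem, arma::fill::zeros);
    std::vector<mat> dX(T);
    mat zeros_hm(ly.h, m, arma::fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      mat dHraw = dH_rec;
      if (emit_all) {
        dHraw += dEmit[t] % lc.Mask[t];
      } else if (t == T - 1) {
        dHraw += dA_last % lc.Mask[t];
      }
      const mat& TC = lc.TC[t];
      mat dO = dHraw % TC;
      mat dC = dC_rec + dHraw % lc.O[t] % (1.0 - TC % TC);
      const mat& Cprev = (t > 0) ? lc.C[t - 1] : zeros_hm;
      mat dI = dC % lc.G[t];
      mat dG = dC % lc.I[t];
      mat dF = dC % Cprev;
      mat dZ(4 * ly.h, m);
      dZ.rows(0, ly.h - 1) = dI % lc.I[t] % (1.0 - lc.I[t]);
      dZ.rows(ly.h, 2 * ly.h - 1) = dF % lc.F[t] % (1.0 - lc.F[t]);
      dZ.rows(2 * ly.h, 3 * ly.h - 1) = dG % (1.0 - lc.G[t] % lc.G[t]);
      dZ.rows(3 * ly.h, 4 * ly.h - 1) = dO % lc.O[t] % (1.0 - lc.O[t]);
      gW += dZ * lc.Xin[t].t();
      const mat& Hprev = (t > 0) ? lc.Hraw[t - 1] : zeros_hm;
      gU += dZ * Hprev.t();
      gb += arma::sum(dZ, 1);
      dH_rec = ly.U.t() * dZ;
      dC_rec = dC % lc.F[t];
      dX[t] = ly.W.t() * dZ;
    }
    grad.layers[l].W = gW;
    grad.layers[l].U = gU;
    grad.layers[l].b = gb;
    dEmit = dX;  // pass down to the layer below
  }
}

// One forward+backward on a batch; returns mean loss and fills grad.
static double loss_and_grad(const Net& net, const mat& Xb,
                            const arma::ivec& yb, double dropout,
                            bool training, Net& grad) {
  int m = Xb.n_rows;
  std::vector<LayerCache> cache;
  mat A = forward(net, Xb, dropout, training, &cache);   // h_last x m
  mat logits = net.Wd * A;
  logits.each_col() += net.bd;
  mat P = softmax_cols(logits);
  double loss = 0.0;
  mat dLogits = P;
  for (int j = 0; j < m; ++j) {
    double p = std::max(P(yb[j], j), 1e-12);
    loss -= std::log(p);
    dLogits(yb[j], j) -= 1.0;
  }
  loss /= m;
  dLogits /= m;
  grad.Wd = dLogits * A.t();
  grad.bd = arma::sum(dLogits, 1);
  mat dA = net.Wd.t() * dLogits;
  backward(net, cache, dA, grad);
  return loss;
}

static Net zeros_like(const Net& net) {
  Net z = net;
  for (auto& ly : z.layers) {
    ly.W.zeros(); ly.U.zeros(); ly.b.zeros();
  }
  z.Wd.zeros();
  z.bd.zeros();
  return z;
}

// Collect aligned pointers over all tensors of a Net (vec handled via mat
// wrappers is avoided by templating on both).
struct TensorRefs {
  std::vector<mat*> mats;
  std::vector<vec*> vecs;
};

static TensorRefs refs_of(Net& net) {
  TensorRefs r;
  for (auto& ly : net.layers) {
    r.mats.push_back(&ly.W);
    r.mats.push_back(&ly.U);
    r.vecs.push_back(&ly.b);
  }
  r.mats.push_back(&net.Wd);
  r.vecs.push_back(&net.bd);
  return r;
}

// [[Rcpp::export]]
arma::mat lstm_predict_cpp(List params, const arma::mat& X, int n_classes) {
  Net net = parse_net(params, n_classes);
  mat A = forward(net, X, 0.0, false, nullptr);
  mat logits = net.Wd * A;
  logits.each_col() += net.bd;
  return softmax_cols(logits).t();  // n x k
}

// [[Rcpp::export]]
List lstm_loss_grad_cpp(List params, const arma::mat& X,
                        const arma::ivec& y, int n_classes) {
  Net net = parse_net(params, n_classes);
  Net grad = zeros_like(net);
  double loss = loss_and_grad(net, X, y, 0.0, false, grad);
  return List::create(_["loss"] = loss, _["grads"] = net_to_list(grad));
}

// [[Rcpp::export]]
List lstm_train_cpp(List params, const arma::mat& X, const arma::ivec& y,
                    int epochs, int batch_size, double lr,
                    std::string optimizer, double dropout, int n_classes) {
  Net net = parse_net(params, n_classes);
  Net grad = zeros_like(net);
  bool adam = (optimizer == "adam");
  Net m1 = zeros_like(net), v1 = zeros_like(net);
  TensorRefs pr = refs_of(net), gr = refs_of(grad);
  TensorRefs mr = refs_of(m1), vr = refs_of(v1);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  int n = X.n_rows;
  double final_loss = 0.0;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int epoch = 0; epoch < epochs; ++epoch) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double epoch_loss = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(start + batch_size, n);
      int m = end - start;
      uvec idx(m);
      arma::ivec yb(m);
      for (int j = 0; j < m; ++j) {
        idx[j] = order[start + j];
        yb[j] = y[order[start + j]];
      }
      mat Xb = X.rows(idx);
      double loss = loss_and_grad(net, Xb, yb, dropout, true, grad);
      epoch_loss += loss * m;
      ++step;
      if (adam) {
        double c1 = 1.0 - std::pow(b1, (double)step);
        double c2 = 1.0 - std::pow(b2, (double)step);
        for (size_t k = 0; k < pr.mats.size(); ++k) {
          mat& g = *gr.mats[k];
          mat& mm = *mr.mats[k];
          mat& vv = *vr.mats[k];
          mm = b1 * mm + (1.0 - b1) * g;
          vv = b2 * vv + (1.0 - b2) * (g % g);
          *pr.mats[k] -= lr * (mm / c1) / (arma::sqrt(vv / c2) + eps);
        }
        for (size_t k = 0; k < pr.vecs.size(); ++k) {
          vec& g = *gr.vecs[k];
          vec& mm = *mr.vecs[k];
          vec& vv = *vr.vecs[k];
          mm = b1 * mm + (1.0 - b1) * g;
          vv = b2 * vv + (1.0 - b2) * (g % g);
          *pr.vecs[k] -= lr * (mm / c1) / (arma::sqrt(vv / c2) + eps);
        }
      } else {
        for (size_t k = 0; k < pr.mats.size(); ++k)
          *pr.mats[k] -= lr * (*gr.mats[k]);
        for (size_t k = 0; k < pr.vecs.size(); ++k)
          *pr.vecs[k] -= lr * (*gr.vecs[k]);
      }
    }
    final_loss = epoch_loss / n;
  }
  return List::create(_["params"] = net_to_list(net),
                      _["final_loss"] = final_loss);
}
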