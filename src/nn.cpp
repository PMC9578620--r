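// Native implementations of the three respiration forecasters: a stacked
// LSTM, a bidirectional LSTM, and an encoder-decoder Transformer with
// look-ahead masking. Forward passes and analytic backpropagation are both
// implemented here; the R layer owns parameter initialization and the Adam
// update. Gradient correctness is pinned by finite-difference tests.
//
// Conventions:
//  - batches of input windows arrive as an R matrix X (B x L), one scalar
//    sample per time step;
//  - parameters are nested R lists of matrices/vectors; gradients are
//    returned with the identical structure so the optimizer can walk both
//    trees in parallel;
//  - transformer activations are held flat as ((B*L) x d) matrices with row
//    index b*L + t, so linear layers, layer norm and the feed-forward nets
//    are single BLAS calls; only attention scores loop over (batch, head);
//  - LSTM gate matrices follow sigma(W . [h, x] + b) with W (H x (H+I));
//    the four gates are fused into one matmul internally.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// ---------------------------------------------------------------------------
// LSTM primitives
// ---------------------------------------------------------------------------

struct LSTMLayerParams {
  mat Wf, Wi, Wc, Wo;  // each H x (H+I)
  vec bf, bi, bc, bo;
  mat Wg;              // fused (4H) x (H+I): rows [f; i; c; o]
  vec bg;
  bool tied;
};

static LSTMLayerParams lstm_layer_params(const List& lp, bool tied) {
  LSTMLayerParams p;
  p.Wf = as<mat>(lp["Wf"]);
  p.Wc = as<mat>(lp["Wc"]);
  p.Wo = as<mat>(lp["Wo"]);
  p.bf = as<vec>(lp["bf"]);
  p.bc = as<vec>(lp["bc"]);
  p.bo = as<vec>(lp["bo"]);
  p.tied = tied;
  if (tied) {  // literal gate equations: input gate shares Wc, bc
    p.Wi = p.Wc;
    p.bi = p.bc;
  } else {
    p.Wi = as<mat>(lp["Wi"]);
    p.bi = as<vec>(lp["bi"]);
  }
  p.Wg = arma::join_cols(arma::join_cols(p.Wf, p.Wi), arma::join_cols(p.Wc, p.Wo));
  p.bg = arma::join_cols(arma::join_cols(p.bf, p.bi), arma::join_cols(p.bc, p.bo));
  return p;
}

struct LSTMLayerCache {
  std::vector<mat> f, i, g, o, C, h, input;  // per time step, each B x dim
};

// one LSTM direction over a sequence of inputs[t] (B x I)
static void lstm_seq_forward(const LSTMLayerParams& p,
                             const std::vector<mat>& inputs,
                             LSTMLayerCache& cc) {
  const int L = inputs.size();
  const int B = inputs[0].n_rows;
  const int H = p.bf.n_elem;
  mat h(B, H, arma::fill::zeros), C(B, H, arma::fill::zeros);
  cc.f.resize(L); cc.i.resize(L); cc.g.resize(L); cc.o.resize(L);
  cc.C.resize(L); cc.h.resize(L); cc.input = inputs;
  for (int t = 0; t < L; ++t) {
    mat z = arma::join_rows(h, inputs[t]);  // [h_{t-1}, x_t]
    mat G = z * p.Wg.t();
    G.each_row() += p.bg.t();
    mat f = sigmoid(G.cols(0, H - 1));
    mat i = sigmoid(G.cols(H, 2 * H - 1));
    mat g = arma::tanh(G.cols(2 * H, 3 * H - 1));
    mat o = sigmoid(G.cols(3 * H, 4 * H - 1));
    C = f % C + i % g;
    h = o % arma::tanh(C);
    cc.f[t] = f; cc.i[t] = i; cc.g[t] = g; cc.o[t] = o;
    cc.C[t] = C; cc.h[t] = h;
  }
}

struct LSTMLayerGrads {
  mat gWg;  // fused, split on export
  vec gbg;
};

// BPTT for one direction; dh_ext[t] flows into h_t, dinputs[t] (B x I) out.
static LSTMLayerGrads lstm_seq_backward(const LSTMLayerParams& p,
                                        const LSTMLayerCache& cc,
                                        const std::vector<mat>& dh_ext,
                                        std::vector<mat>& dinputs) {
  const int L = cc.h.size();
  const int B = cc.h[0].n_rows;
  const int H = p.bf.n_elem;
  const int I = cc.input[0].n_cols;
  LSTMLayerGrads gr;
  gr.gWg.zeros(4 * H, H + I);
  gr.gbg.zeros(4 * H);
  dinputs.assign(L, mat(B, I, arma::fill::zeros));

  mat dh_carry(B, H, arma::fill::zeros), dC(B, H, arma::fill::zeros);
  mat dzall(B, 4 * H);
  for (int t = L - 1; t >= 0; --t) {
    mat dh = dh_ext[t] + dh_carry;
    mat tC = arma::tanh(cc.C[t]);
    mat do_ = dh % tC;
    dC += dh % cc.o[t] % (1.0 - tC % tC);
    mat Cprev = (t > 0) ? cc.C[t - 1] : mat(B, H, arma::fill::zeros);
    dzall.cols(0, H - 1) = (dC % Cprev) % cc.f[t] % (1.0 - cc.f[t]);
    dzall.cols(H, 2 * H - 1) = (dC % cc.g[t]) % cc.i[t] % (1.0 - cc.i[t]);
    dzall.cols(2 * H, 3 * H - 1) = (dC % cc.i[t]) % (1.0 - cc.g[t] % cc.g[t]);
    dzall.cols(3 * H, 4 * H - 1) = do_ % cc.o[t] % (1.0 - cc.o[t]);
    dC = dC % cc.f[t];  // becomes dC_{t-1}
    mat hprev = (t > 0) ? cc.h[t - 1] : mat(B, H, arma::fill::zeros);
    mat z = arma::join_rows(hprev, cc.input[t]);
    gr.gWg += dzall.t() * z;
    gr.gbg += arma::sum(dzall, 0).t();
    mat dZ = dzall * p.Wg;
    dh_carry = dZ.cols(0, H - 1);
    dinputs[t] = dZ.cols(H, H + I - 1);
  }
  return gr;
}

static List lstm_layer_grads_list(const LSTMLayerGrads& gr, const LSTMLayerParams& p) {
  const int H = p.bf.n_elem;
  mat gWf = gr.gWg.rows(0, H - 1);
  mat gWi = gr.gWg.rows(H, 2 * H - 1);
  mat gWc = gr.gWg.rows(2 * H, 3 * H - 1);
  mat gWo = gr.gWg.rows(3 * H, 4 * H - 1);
  vec gbf = gr.gbg.subvec(0, H - 1);
  vec gbi = gr.gbg.subvec(H, 2 * H - 1);
  vec gbc = gr.gbg.subvec(2 * H, 3 * H - 1);
  vec gbo = gr.gbg.subvec(3 * H, 4 * H - 1);
  if (p.tied) {  // fold input-gate gradients into the shared candidate params
    gWc += gWi; gWi.zeros();
    gbc += gbi; gbi.zeros();
  }
  return List::create(_["Wf"] = gWf, _["Wi"] = gWi, _["Wc"] = gWc,
                      _["Wo"] = gWo, _["bf"] = gbf, _["bi"] = gbi,
                      _["bc"] = gbc, _["bo"] = gbo);
}

static std::vector<mat> matrix_to_seq(const mat& X) {
  // X (B x L) of scalar samples -> L inputs of shape (B x 1)
  std::vector<mat> seq(X.n_cols);
  for (arma::uword t = 0; t < X.n_cols; ++t) seq[t] = X.col(t);
  return seq;
}

// ---------------------------------------------------------------------------
// Exposed primitive: one LSTM cell step (vector form)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_lstm_cell(const arma::vec& x, const arma::vec& h_prev,
                   const arma::vec& C_prev, const List& layer, bool tied) {
  LSTMLayerParams p = lstm_layer_params(layer, tied);
  if (p.Wf.n_cols != h_prev.n_elem + x.n_elem || p.bf.n_elem != h_prev.n_elem)
    stop("dimension mismatch in lstm cell step");
  vec z = arma::join_cols(h_prev, x);
  vec f = 1.0 / (1.0 + arma::exp(-(p.Wf * z + p.bf)));
  vec i = 1.0 / (1.0 + arma::exp(-(p.Wi * z + p.bi)));
  vec g = arma::tanh(p.Wc * z + p.bc);
  vec o = 1.0 / (1.0 + arma::exp(-(p.Wo * z + p.bo)));
  vec C = f % C_prev + i % g;
  vec h = o % arma::tanh(C);
  return List::create(_["h"] = h, _["C"] = C, _["f"] = f, _["i"] = i,
                      _["g"] = g, _["o"] = o);
}

// ---------------------------------------------------------------------------
// Stacked LSTM model
// ---------------------------------------------------------------------------

struct LSTMStack {
  std::vector<LSTMLayerParams> layers;
  vec wout;
  double bout;
};

static LSTMStack lstm_stack_params(const List& params, bool tied) {
  LSTMStack m;
  List layers = params["layers"];
  for (int l = 0; l < layers.size(); ++l)
    m.layers.push_back(lstm_layer_params(layers[l], tied));
  m.wout = as<vec>(params["wout"]);
  m.bout = as<double>(params["bout"]);
  return m;
}

static vec lstm_stack_forward(const LSTMStack& m, const mat& X,
                              std::vector<LSTMLayerCache>& caches) {
  std::vector<mat> seq = matrix_to_seq(X);
  caches.resize(m.layers.size());
  for (size_t l = 0; l < m.layers.size(); ++l) {
    lstm_seq_forward(m.layers[l], seq, caches[l]);
    seq = caches[l].h;
  }
  const mat& h_top = seq.back();
  return h_top * m.wout + m.bout;
}

// [[Rcpp::export]]
arma::vec cpp_lstm_predict(const List& params, const arma::mat& X, bool tied) {
  std::vector<LSTMLayerCache> caches;
  return lstm_stack_forward(lstm_stack_params(params, tied), X, caches);
}

// [[Rcpp::export]]
List cpp_lstm_grad(const List& params, const arma::mat& X,
                   const arma::vec& y, bool tied) {
  LSTMStack m = lstm_stack_params(params, tied);
  std::vector<LSTMLayerCache> caches;
  vec pred = lstm_stack_forward(m, X, caches);
  const int B = X.n_rows, L = X.n_cols;
  const int H = m.wout.n_elem;
  const int nl = m.layers.size();
  vec resid = pred - y;
  double loss = arma::dot(resid, resid) / B;
  vec dpred = 2.0 * resid / B;

  vec gwout = caches[nl - 1].h[L - 1].t() * dpred;
  double gbout = arma::sum(dpred);

  std::vector<mat> dh_ext(L, mat(B, H, arma::fill::zeros));
  dh_ext[L - 1] = dpred * m.wout.t();
  List glayers(nl);
  for (int l = nl - 1; l >= 0; --l) {
    std::vector<mat> dinputs;
    LSTMLayerGrads gr = lstm_seq_backward(m.layers[l], caches[l], dh_ext, dinputs);
    glayers[l] = lstm_layer_grads_list(gr, m.layers[l]);
    dh_ext = dinputs;  // gradient w.r.t. the layer below's hidden sequence
  }
  return List::create(
      _["loss"] = loss, _["pred"] = pred,
      _["grads"] = List::create(_["layers"] = glayers, _["wout"] = gwout,
                                _["bout"] = gbout));
}

// ---------------------------------------------------------------------------
// Bidirectional LSTM model
// ---------------------------------------------------------------------------

struct BiLayerParams {
  LSTMLayerParams fwd, bwd;
  mat Wfy, Wby;
  vec by;
};

struct BiStack {
  std::vector<BiLayerParams> layers;
  vec wout;
  double bout;
};

static BiStack bilstm_params(const List& params, bool tied) {
  BiStack m;
  List layers = params["layers"];
  for (int l = 0; l < layers.size(); ++l) {
    List lp = layers[l];
    BiLayerParams bp;
    bp.fwd = lstm_layer_params(lp["fwd"], tied);
    bp.bwd = lstm_layer_params(lp["bwd"], tied);
    bp.Wfy = as<mat>(lp["Wfy"]);
    bp.Wby = as<mat>(lp["Wby"]);
    bp.by = as<vec>(lp["by"]);
    m.layers.push_back(bp);
  }
  m.wout = as<vec>(params["wout"]);
  m.bout = as<double>(params["bout"]);
  return m;
}

struct BiLayerCache {
  LSTMLayerCache fc, bc;          // bc runs over time-reversed input
  std::vector<mat> y;             // combined outputs per time step
};

// y_t = Wfy h_fwd_t + Wby h_bwd_t + by; h_bwd from the time-reversed pass
static void bilstm_layer_forward(const BiLayerParams& p,
                                 const std::vector<mat>& inputs,
                                 BiLayerCache& cc) {
  const int L = inputs.size();
  lstm_seq_forward(p.fwd, inputs, cc.fc);
  std::vector<mat> rev(inputs.rbegin(), inputs.rend());
  lstm_seq_forward(p.bwd, rev, cc.bc);
  cc.y.resize(L);
  const int B = inputs[0].n_rows;
  for (int t = 0; t < L; ++t) {
    cc.y[t] = cc.fc.h[t] * p.Wfy.t() + cc.bc.h[L - 1 - t] * p.Wby.t()
              + arma::repmat(p.by.t(), B, 1);
  }
}

static vec bilstm_forward(const BiStack& m, const mat& X,
                          std::vector<BiLayerCache>& caches) {
  std::vector<mat> seq = matrix_to_seq(X);
  caches.resize(m.layers.size());
  for (size_t l = 0; l < m.layers.size(); ++l) {
    bilstm_layer_forward(m.layers[l], seq, caches[l]);
    seq = caches[l].y;
  }
  return seq.back() * m.wout + m.bout;
}

// [[Rcpp::export]]
arma::vec cpp_bilstm_predict(const List& params, const arma::mat& X, bool tied) {
  std::vector<BiLayerCache> caches;
  return bilstm_forward(bilstm_params(params, tied), X, caches);
}

// [[Rcpp::export]]
List cpp_bilstm_grad(const List& params, const arma::mat& X,
                     const arma::vec& y, bool tied) {
  BiStack m = bilstm_params(params, tied);
  std::vector<BiLayerCache> caches;
  vec pred = bilstm_forward(m, X, caches);
  const int B = X.n_rows, L = X.n_cols;
  const int nl = m.layers.size();
  vec resid = pred - y;
  double loss = arma::dot(resid, resid) / B;
  vec dpred = 2.0 * resid / B;

  vec gwout = caches[nl - 1].y[L - 1].t() * dpred;
  double gbout = arma::sum(dpred);

  const int Hout = m.wout.n_elem;
  std::vector<mat> dy(L, mat(B, Hout, arma::fill::zeros));
  dy[L - 1] = dpred * m.wout.t();

  List glayers(nl);
  for (int l = nl - 1; l >= 0; --l) {
    const BiLayerParams& p = m.layers[l];
    const BiLayerCache& cc = caches[l];
    const int H = p.by.n_elem;
    mat gWfy(arma::size(p.Wfy), arma::fill::zeros);
    mat gWby(arma::size(p.Wby), arma::fill::zeros);
    vec gby(H, arma::fill::zeros);
    std::vector<mat> dhf(L, mat(B, H, arma::fill::zeros));
    std::vector<mat> dhb_rev(L, mat(B, H, arma::fill::zeros));
    for (int t = 0; t < L; ++t) {
      gWfy += dy[t].t() * cc.fc.h[t];
      gWby += dy[t].t() * cc.bc.h[L - 1 - t];
      gby += arma::sum(dy[t], 0).t();
      dhf[t] = dy[t] * p.Wfy;
      dhb_rev[L - 1 - t] = dy[t] * p.Wby;
    }
    std::vector<mat> dinf, dinb_rev;
    LSTMLayerGrads gf = lstm_seq_backward(p.fwd, cc.fc, dhf, dinf);
    LSTMLayerGrads gb = lstm_seq_backward(p.bwd, cc.bc, dhb_rev, dinb_rev);
    std::vector<mat> dinputs(L);
    for (int t = 0; t < L; ++t) dinputs[t] = dinf[t] + dinb_rev[L - 1 - t];
    glayers[l] = List::create(
        _["fwd"] = lstm_layer_grads_list(gf, p.fwd),
        _["bwd"] = lstm_layer_grads_list(gb, p.bwd),
        _["Wfy"] = gWfy, _["Wby"] = gWby, _["by"] = gby);
    dy = dinputs;
  }
  return List::create(
      _["loss"] = loss, _["pred"] = pred,
      _["grads"] = List::create(_["layers"] = glayers, _["wout"] = gwout,
                                _["bout"] = gbout));
}

// ---------------------------------------------------------------------------
// Attention / Transformer
// ---------------------------------------------------------------------------

static mat softmax_rows(mat S) {
  S.each_col() -= arma::max(S, 1);
  S = arma::exp(S);
  S.each_col() /= arma::sum(S, 1);
  return S;
}

// Exposed primitive: scaled dot-product attention on plain matrices.
// [[Rcpp::export]]
List cpp_attention(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                   Rcpp::Nullable<Rcpp::NumericMatrix> mask) {
  if (Q.n_cols != K.n_cols) stop("Q and K must share their feature dimension");
  if (K.n_rows != V.n_rows) stop("K and V must share their sequence length");
  mat S = Q * K.t() / std::sqrt((double)K.n_cols);
  if (mask.isNotNull()) {
    mat M = as<mat>(mask.get());
    if (M.n_rows != S.n_rows || M.n_cols != S.n_cols)
      stop("mask must be (nrow(Q) x nrow(K))");
    S += M;
  }
  mat A = softmax_rows(S);
  return List::create(_["context"] = A * V, _["weights"] = A);
}

struct AttnParams { mat Wq, Wk, Wv, Wo; vec bq, bk, bv, bo; };
struct LNParams { vec g, b; };
struct FFParams { mat W1, W2; vec b1, b2; };

static AttnParams attn_params(const List& lp) {
  AttnParams p;
  p.Wq = as<mat>(lp["Wq"]); p.Wk = as<mat>(lp["Wk"]);
  p.Wv = as<mat>(lp["Wv"]); p.Wo = as<mat>(lp["Wo"]);
  p.bq = as<vec>(lp["bq"]); p.bk = as<vec>(lp["bk"]);
  p.bv = as<vec>(lp["bv"]); p.bo = as<vec>(lp["bo"]);
  return p;
}
static LNParams ln_params(const List& lp) {
  LNParams p; p.g = as<vec>(lp["g"]); p.b = as<vec>(lp["b"]); return p;
}
static FFParams ff_params(const List& lp) {
  FFParams p;
  p.W1 = as<mat>(lp["W1"]); p.W2 = as<mat>(lp["W2"]);
  p.b1 = as<vec>(lp["b1"]); p.b2 = as<vec>(lp["b2"]);
  return p;
}

struct AttnGrads { mat Wq, Wk, Wv, Wo; vec bq, bk, bv, bo;
  void init(const AttnParams& p) {
    Wq.zeros(arma::size(p.Wq)); Wk.zeros(arma::size(p.Wk));
    Wv.zeros(arma::size(p.Wv)); Wo.zeros(arma::size(p.Wo));
    bq.zeros(p.bq.n_elem); bk.zeros(p.bk.n_elem);
    bv.zeros(p.bv.n_elem); bo.zeros(p.bo.n_elem);
  }
  List as_list() const {
    return List::create(_["Wq"] = Wq, _["Wk"] = Wk, _["Wv"] = Wv, _["Wo"] = Wo,
                        _["bq"] = bq, _["bk"] = bk, _["bv"] = bv, _["bo"] = bo);
  }
};
struct LNGrads { vec g, b;
  void init(const LNParams& p) { g.zeros(p.g.n_elem); b.zeros(p.b.n_elem); }
  List as_list() const { return List::create(_["g"] = g, _["b"] = b); }
};
struct FFGrads { mat W1, W2; vec b1, b2;
  void init(const FFParams& p) {
    W1.zeros(arma::size(p.W1)); W2.zeros(arma::size(p.W2));
    b1.zeros(p.b1.n_elem); b2.zeros(p.b2.n_elem);
  }
  List as_list() const {
    return List::create(_["W1"] = W1, _["b1"] = b1, _["W2"] = W2, _["b2"] = b2);
  }
};

// Multi-head attention on flat activations ((B*Lq) x d), row = b*Lq + t.
struct MHACache {
  mat Q, K, V;      // projected, flat
  mat A;            // attention rows stacked: ((B*nh*Lq) x Lk)
  mat Ocat;         // concatenated head outputs before Wo, flat
};

static mat mha_forward(const AttnParams& p, const mat& Xq, const mat& Xkv,
                       int B, int Lq, int Lk, int nh, bool masked,
                       MHACache& cc) {
  const int d = Xq.n_cols;
  const int dk = d / nh;
  const double scale = 1.0 / std::sqrt((double)dk);
  cc.Q = Xq * p.Wq;  cc.Q.each_row() += p.bq.t();
  cc.K = Xkv * p.Wk; cc.K.each_row() += p.bk.t();
  cc.V = Xkv * p.Wv; cc.V.each_row() += p.bv.t();
  cc.A.set_size(B * nh * Lq, Lk);
  cc.Ocat.set_size(B * Lq, d);
  // hand-rolled per-(batch, head) kernels: the blocks are tiny (L x dk), so
  // plain loops beat BLAS-call and temporary-allocation overhead by a wide
  // margin at batch 300
  std::vector<double> S(Lq * Lk);
  for (int b = 0; b < B; ++b) {
    const int q0 = b * Lq, k0 = b * Lk;
    for (int h = 0; h < nh; ++h) {
      const int c0 = h * dk;
      for (int j = 0; j < Lk; ++j) {
        for (int i = 0; i < Lq; ++i) {
          double acc = 0;
          for (int dd = 0; dd < dk; ++dd)
            acc += cc.Q.colptr(c0 + dd)[q0 + i] * cc.K.colptr(c0 + dd)[k0 + j];
          S[i + Lq * j] = acc * scale;
        }
      }
      if (masked) {  // look-ahead mask: position i may attend to j <= i only
        for (int j = 0; j < Lk; ++j)
          for (int i = 0; i < j && i < Lq; ++i) S[i + Lq * j] = -1e30;
      }
      const int a0 = (b * nh + h) * Lq;
      for (int i = 0; i < Lq; ++i) {
        double mx = S[i];
        for (int j = 1; j < Lk; ++j) mx = std::max(mx, S[i + Lq * j]);
        double sum = 0;
        for (int j = 0; j < Lk; ++j) {
          double e = std::exp(S[i + Lq * j] - mx);
          S[i + Lq * j] = e;
          sum += e;
        }
        for (int j = 0; j < Lk; ++j) {
          S[i + Lq * j] /= sum;
          cc.A.colptr(j)[a0 + i] = S[i + Lq * j];
        }
      }
      for (int dd = 0; dd < dk; ++dd) {
        const double* vcol = cc.V.colptr(c0 + dd) + k0;
        double* ocol = cc.Ocat.colptr(c0 + dd) + q0;
        for (int i = 0; i < Lq; ++i) {
          double acc = 0;
          for (int j = 0; j < Lk; ++j) acc += S[i + Lq * j] * vcol[j];
          ocol[i] = acc;
        }
      }
    }
  }
  mat out = cc.Ocat * p.Wo;
  out.each_row() += p.bo.t();
  return out;
}

// Backward: accumulates into dXq / dXkv (may alias) and parameter grads.
static void mha_backward(const AttnParams& p, const MHACache& cc,
                         const mat& Xq, const mat& Xkv, const mat& dOut,
                         int B, int Lq, int Lk, int nh,
                         mat& dXq, mat& dXkv, AttnGrads& gr) {
  const int d = Xq.n_cols;
  const int dk = d / nh;
  const double scale = 1.0 / std::sqrt((double)dk);
  gr.Wo += cc.Ocat.t() * dOut;
  gr.bo += arma::sum(dOut, 0).t();
  mat dOcat = dOut * p.Wo.t();
  mat dQ(arma::size(cc.Q), arma::fill::none);
  mat dK(arma::size(cc.K), arma::fill::none);
  mat dV(arma::size(cc.V), arma::fill::none);
  // hand-rolled per-(batch, head) kernels; see the forward pass
  std::vector<double> dA(Lq * Lk), dS(Lq * Lk);
  for (int b = 0; b < B; ++b) {
    const int q0 = b * Lq, k0 = b * Lk;
    for (int h = 0; h < nh; ++h) {
      const int c0 = h * dk;
      const int a0 = (b * nh + h) * Lq;
      // dA = dOh V', then softmax backward: dS = A o (dA - rowsum(dA o A));
      // masked entries have A == 0, so dS vanishes there
      for (int j = 0; j < Lk; ++j) {
        for (int i = 0; i < Lq; ++i) {
          double acc = 0;
          for (int dd = 0; dd < dk; ++dd)
            acc += dOcat.colptr(c0 + dd)[q0 + i] * cc.V.colptr(c0 + dd)[k0 + j];
          dA[i + Lq * j] = acc;
        }
      }
      for (int i = 0; i < Lq; ++i) {
        double r = 0;
        for (int j = 0; j < Lk; ++j)
          r += dA[i + Lq * j] * cc.A.colptr(j)[a0 + i];
        for (int j = 0; j < Lk; ++j) {
          double a = cc.A.colptr(j)[a0 + i];
          dS[i + Lq * j] = a * (dA[i + Lq * j] - r);
        }
      }
      for (int dd = 0; dd < dk; ++dd) {
        const double* kcol = cc.K.colptr(c0 + dd) + k0;
        const double* qcol = cc.Q.colptr(c0 + dd) + q0;
        const double* ocol = dOcat.colptr(c0 + dd) + q0;
        double* dqcol = dQ.colptr(c0 + dd) + q0;
        double* dkcol = dK.colptr(c0 + dd) + k0;
        double* dvcol = dV.colptr(c0 + dd) + k0;
        for (int i = 0; i < Lq; ++i) {
          double acc = 0;
          for (int j = 0; j < Lk; ++j) acc += dS[i + Lq * j] * kcol[j];
          dqcol[i] = acc * scale;
        }
        for (int j = 0; j < Lk; ++j) {
          double accK = 0, accV = 0;
          for (int i = 0; i < Lq; ++i) {
            accK += dS[i + Lq * j] * qcol[i];
            accV += cc.A.colptr(j)[a0 + i] * ocol[i];
          }
          dkcol[j] = accK * scale;
          dvcol[j] = accV;
        }
      }
    }
  }
  gr.Wq += Xq.t() * dQ;  gr.bq += arma::sum(dQ, 0).t();
  gr.Wk += Xkv.t() * dK; gr.bk += arma::sum(dK, 0).t();
  gr.Wv += Xkv.t() * dV; gr.bv += arma::sum(dV, 0).t();
  dXq += dQ * p.Wq.t();
  dXkv += dK * p.Wk.t() + dV * p.Wv.t();
}

// Layer normalization over the feature dimension, per token (row).
struct LNCache { mat xhat; vec inv_sigma; };

static const double LN_EPS = 1e-5;

static mat ln_forward(const LNParams& p, const mat& X, LNCache& cc) {
  vec mu = arma::mean(X, 1);
  mat centered = X;
  centered.each_col() -= mu;
  vec v = arma::mean(centered % centered, 1);
  cc.inv_sigma = 1.0 / arma::sqrt(v + LN_EPS);
  cc.xhat = centered;
  cc.xhat.each_col() %= cc.inv_sigma;
  mat y = cc.xhat;
  y.each_row() %= p.g.t();
  y.each_row() += p.b.t();
  return y;
}

static mat ln_backward(const LNParams& p, const LNCache& cc, const mat& dY,
                       LNGrads& gr) {
  gr.g += arma::sum(dY % cc.xhat, 0).t();
  gr.b += arma::sum(dY, 0).t();
  mat dxhat = dY;
  dxhat.each_row() %= p.g.t();
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % cc.xhat, 1);
  mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= cc.xhat.each_col() % m2;
  dx.each_col() %= cc.inv_sigma;
  return dx;
}

struct FFCache { mat X, H1; };

static mat ff_forward(const FFParams& p, const mat& X, FFCache& cc) {
  cc.X = X;
  cc.H1 = X * p.W1;
  cc.H1.each_row() += p.b1.t();
  cc.H1.elem(arma::find(cc.H1 < 0)).zeros();  // ReLU
  mat out = cc.H1 * p.W2;
  out.each_row() += p.b2.t();
  return out;
}

static mat ff_backward(const FFParams& p, const FFCache& cc, const mat& dY,
                       FFGrads& gr) {
  gr.W2 += cc.H1.t() * dY;
  gr.b2 += arma::sum(dY, 0).t();
  mat dH1 = dY * p.W2.t();
  dH1.elem(arma::find(cc.H1 == 0)).zeros();
  gr.W1 += cc.X.t() * dH1;
  gr.b1 += arma::sum(dH1, 0).t();
  return dH1 * p.W1.t();
}

struct EncLayerParams { AttnParams attn; LNParams ln1; FFParams ff; LNParams ln2; };
struct DecLayerParams {
  AttnParams self_attn; LNParams ln1; AttnParams cross; LNParams ln2;
  FFParams ff; LNParams ln3;
};

struct EncLayerCache {
  mat Xin, N1;
  MHACache attn; LNCache ln1; FFCache ff; LNCache ln2;
};
struct DecLayerCache {
  mat Xin, N1, N2;
  MHACache self_attn; LNCache ln1; MHACache cross; LNCache ln2;
  FFCache ff; LNCache ln3;
};

struct TransformerParams {
  vec wemb, bemb;
  std::vector<EncLayerParams> enc;
  std::vector<DecLayerParams> dec;
  vec wout;
  double bout;
  int nh;
};

static TransformerParams transformer_params(const List& params, int nh) {
  TransformerParams m;
  m.wemb = as<vec>(params["wemb"]);
  m.bemb = as<vec>(params["bemb"]);
  List enc = params["enc"];
  for (int l = 0; l < enc.size(); ++l) {
    List lp = enc[l];
    EncLayerParams e;
    e.attn = attn_params(lp["attn"]); e.ln1 = ln_params(lp["ln1"]);
    e.ff = ff_params(lp["ff"]); e.ln2 = ln_params(lp["ln2"]);
    m.enc.push_back(e);
  }
  List dec = params["dec"];
  for (int l = 0; l < dec.size(); ++l) {
    List lp = dec[l];
    DecLayerParams d;
    d.self_attn = attn_params(lp["self_attn"]); d.ln1 = ln_params(lp["ln1"]);
    d.cross = attn_params(lp["cross"]); d.ln2 = ln_params(lp["ln2"]);
    d.ff = ff_params(lp["ff"]); d.ln3 = ln_params(lp["ln3"]);
    m.dec.push_back(d);
  }
  m.wout = as<vec>(params["wout"]);
  m.bout = as<double>(params["bout"]);
  m.nh = nh;
  return m;
}

// sinusoidal position encoding, (L x d)
static mat position_encoding(int L, int d) {
  mat pe(L, d);
  for (int t = 0; t < L; ++t) {
    for (int j = 0; j < d; j += 2) {
      double angle = t / std::pow(10000.0, (double)j / d);
      pe(t, j) = std::sin(angle);
      if (j + 1 < d) pe(t, j + 1) = std::cos(angle);
    }
  }
  return pe;
}

// scalar samples (B x L) -> flat embedded activations ((B*L) x d), row b*L+t
static mat embed(const mat& X, const vec& wemb, const vec& bemb, const mat& pe) {
  const int B = X.n_rows, L = X.n_cols;
  vec xflat = arma::vectorise(X.t());  // order: t fastest, then b
  mat E = xflat * wemb.t();
  E.each_row() += bemb.t();
  E += arma::repmat(pe, B, 1);
  return E;
}

struct TransformerCache {
  mat E, D0;                 // embedded encoder / decoder inputs
  std::vector<EncLayerCache> enc;
  std::vector<DecLayerCache> dec;
  mat M;                     // encoder output (memory)
  mat Dout;                  // final decoder output
};

static mat enc_layer_forward(const EncLayerParams& p, const mat& X,
                             int B, int L, int nh, EncLayerCache& cc) {
  cc.Xin = X;
  mat A = mha_forward(p.attn, X, X, B, L, L, nh, false, cc.attn);
  cc.N1 = ln_forward(p.ln1, X + A, cc.ln1);
  mat F = ff_forward(p.ff, cc.N1, cc.ff);
  return ln_forward(p.ln2, cc.N1 + F, cc.ln2);
}

static mat dec_layer_forward(const DecLayerParams& p, const mat& X,
                             const mat& M, int B, int L, int nh,
                             DecLayerCache& cc) {
  cc.Xin = X;
  mat A = mha_forward(p.self_attn, X, X, B, L, L, nh, true, cc.self_attn);
  cc.N1 = ln_forward(p.ln1, X + A, cc.ln1);
  mat C = mha_forward(p.cross, cc.N1, M, B, L, L, nh, false, cc.cross);
  cc.N2 = ln_forward(p.ln2, cc.N1 + C, cc.ln2);
  mat F = ff_forward(p.ff, cc.N2, cc.ff);
  return ln_forward(p.ln3, cc.N2 + F, cc.ln3);
}

// decoder input: the window delayed by one position (first sample repeated as
// the start token), giving the stated one-position offset between decoder
// input and supervised output
static mat decoder_input(const mat& X) {
  mat D = X;
  if (X.n_cols > 1) D.cols(1, X.n_cols - 1) = X.cols(0, X.n_cols - 2);
  return D;
}

static vec transformer_forward_impl(const TransformerParams& m, const mat& X,
                                    TransformerCache& cc) {
  const int B = X.n_rows, L = X.n_cols, d = m.wemb.n_elem;
  mat pe = position_encoding(L, d);
  cc.E = embed(X, m.wemb, m.bemb, pe);
  mat cur = cc.E;
  cc.enc.resize(m.enc.size());
  for (size_t l = 0; l < m.enc.size(); ++l)
    cur = enc_layer_forward(m.enc[l], cur, B, L, m.nh, cc.enc[l]);
  cc.M = cur;
  cc.D0 = embed(decoder_input(X), m.wemb, m.bemb, pe);
  cur = cc.D0;
  cc.dec.resize(m.dec.size());
  for (size_t l = 0; l < m.dec.size(); ++l)
    cur = dec_layer_forward(m.dec[l], cur, cc.M, B, L, m.nh, cc.dec[l]);
  cc.Dout = cur;
  vec pred(B);
  for (int b = 0; b < B; ++b)
    pred(b) = arma::dot(cur.row(b * L + L - 1).t(), m.wout) + m.bout;
  return pred;
}

// [[Rcpp::export]]
arma::vec cpp_transformer_predict(const List& params, const arma::mat& X, int n_heads) {
  TransformerCache cc;
  return transformer_forward_impl(transformer_params(params, n_heads), X, cc);
}

// [[Rcpp::export]]
List cpp_transformer_grad(const List& params, const arma::mat& X,
                          const arma::vec& y, int n_heads) {
  TransformerParams m = transformer_params(params, n_heads);
  TransformerCache cc;
  vec pred = transformer_forward_impl(m, X, cc);
  const int B = X.n_rows, L = X.n_cols, d = m.wemb.n_elem;
  vec resid = pred - y;
  double loss = arma::dot(resid, resid) / B;
  vec dpred = 2.0 * resid / B;

  vec gwout(d, arma::fill::zeros);
  double gbout = arma::sum(dpred);
  mat dDout(B * L, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    gwout += cc.Dout.row(b * L + L - 1).t() * dpred(b);
    dDout.row(b * L + L - 1) = dpred(b) * m.wout.t();
  }

  // decoder stack backward, accumulating memory gradient from cross-attention
  mat dM(arma::size(cc.M), arma::fill::zeros);
  List gdec(m.dec.size());
  mat dcur = dDout;
  for (int l = (int)m.dec.size() - 1; l >= 0; --l) {
    const DecLayerParams& p = m.dec[l];
    DecLayerCache& lc = cc.dec[l];
    AttnGrads ga_self, ga_cross; ga_self.init(p.self_attn); ga_cross.init(p.cross);
    LNGrads g1, g2, g3; g1.init(p.ln1); g2.init(p.ln2); g3.init(p.ln3);
    FFGrads gff; gff.init(p.ff);

    mat dR3 = ln_backward(p.ln3, lc.ln3, dcur, g3);
    mat dN2 = dR3;  // residual branch
    dN2 += ff_backward(p.ff, lc.ff, dR3, gff);
    mat dR2 = ln_backward(p.ln2, lc.ln2, dN2, g2);
    mat dN1 = dR2;
    mha_backward(p.cross, lc.cross, lc.N1, cc.M, dR2, B, L, L, m.nh,
                 dN1, dM, ga_cross);
    mat dR1 = ln_backward(p.ln1, lc.ln1, dN1, g1);
    mat dX = dR1;
    mha_backward(p.self_attn, lc.self_attn, lc.Xin, lc.Xin, dR1, B, L, L, m.nh,
                 dX, dX, ga_self);
    gdec[l] = List::create(
        _["self_attn"] = ga_self.as_list(), _["ln1"] = g1.as_list(),
        _["cross"] = ga_cross.as_list(), _["ln2"] = g2.as_list(),
        _["ff"] = gff.as_list(), _["ln3"] = g3.as_list());
    dcur = dX;
  }
  mat dD0 = dcur;

  // encoder stack backward
  List genc(m.enc.size());
  dcur = dM;
  for (int l = (int)m.enc.size() - 1; l >= 0; --l) {
    const EncLayerParams& p = m.enc[l];
    EncLayerCache& lc = cc.enc[l];
    AttnGrads ga; ga.init(p.attn);
    LNGrads g1, g2; g1.init(p.ln1); g2.init(p.ln2);
    FFGrads gff; gff.init(p.ff);
    mat dR2 = ln_backward(p.ln2, lc.ln2, dcur, g2);
    mat dN1 = dR2;
    dN1 += ff_backward(p.ff, lc.ff, dR2, gff);
    mat dR1 = ln_backward(p.ln1, lc.ln1, dN1, g1);
    mat dX = dR1;
    mha_backward(p.attn, lc.attn, lc.Xin, lc.Xin, dR1, B, L, L, m.nh,
                 dX, dX, ga);
    genc[l] = List::create(_["attn"] = ga.as_list(), _["ln1"] = g1.as_list(),
                           _["ff"] = gff.as_list(), _["ln2"] = g2.as_list());
    dcur = dX;
  }
  mat dE = dcur;

  // embedding gradients from both encoder and decoder inputs
  vec xflat = arma::vectorise(X.t());
  vec dflat = arma::vectorise(decoder_input(X).t());
  vec gwemb = dE.t() * xflat + dD0.t() * dflat;
  vec gbemb = arma::sum(dE, 0).t() + arma::sum(dD0, 0).t();

  return List::create(
      _["loss"] = loss, _["pred"] = pred,
      _["grads"] = List::create(_["wemb"] = gwemb, _["bemb"] = gbemb,
                                _["enc"] = genc, _["dec"] = gdec,
                                _["wout"] = gwout, _["bout"] = gbout));
}
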