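// Batched forward/backward/Adam core for the gated dilated-convolution
// per-base classifier. The batch is flattened position-major: row
// (t-1)*B + b holds position t of read b, so a shift by s*B rows moves every
// read s positions at once and never crosses read boundaries. All maths
// mirrors the documented model: token embeddings, a residual ReLU-MLP
// quality block, L gated dilated conv layers (tanh filter x sigmoid gate,
// residual), a two-layer head and a two-class softmax; read-mean
// cross-entropy loss averaged over the batch.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int PAD_ID = 6;

static arma::mat as_view(SEXP x) {
  NumericVector v(x);
  SEXP dim = Rf_getAttrib(x, R_DimSymbol);
  int nr, nc;
  if (Rf_isNull(dim)) {
    nr = v.size(); nc = 1;
  } else {
    IntegerVector d(dim);
    nr = d[0]; nc = d[1];
  }
  return arma::mat(v.begin(), nr, nc, false, true);
}

static inline void relu_inplace(arma::mat& m) {
  double* p = m.memptr();
  const arma::uword n = m.n_elem;
  for (arma::uword i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
}

static inline void sigmoid_inplace(arma::mat& m) {
  double* p = m.memptr();
  const arma::uword n = m.n_elem;
  for (arma::uword i = 0; i < n; ++i) p[i] = 1.0 / (1.0 + std::exp(-p[i]));
}

static inline void tanh_inplace(arma::mat& m) {
  double* p = m.memptr();
  const arma::uword n = m.n_elem;
  for (arma::uword i = 0; i < n; ++i) p[i] = std::tanh(p[i]);
}

static void zero_rows(arma::mat& m, const std::vector<int>& rows) {
  for (int r : rows) m.row(r).zeros();
}

// K row-shifted copies of X side by side (im2col), zero-filled at the edges
static void conv_cols(const arma::mat& X, int K, int step, arma::mat& Xc) {
  const int R = X.n_rows, D = X.n_cols;
  const int half = (K - 1) / 2;
  Xc.zeros(R, K * D);
  for (int k = 0; k < K; ++k) {
    const int s = (k - half) * step;
    const int c0 = k * D;
    if (s == 0) {
      Xc.cols(c0, c0 + D - 1) = X;
    } else if (s > 0 && s < R) {
      Xc.submat(s, c0, R - 1, c0 + D - 1) = X.rows(0, R - 1 - s);
    } else if (s < 0 && -s < R) {
      Xc.submat(0, c0, R - 1 + s, c0 + D - 1) = X.rows(-s, R - 1);
    }
  }
}

// transpose of conv_cols: fold an im2col gradient back onto positions
static void conv_fold(const arma::mat& dXc, int K, int step, int D,
                      arma::mat& dX) {
  const int R = dXc.n_rows;
  const int half = (K - 1) / 2;
  for (int k = 0; k < K; ++k) {
    const int s = (k - half) * step;
    const int c0 = k * D;
    if (s == 0) {
      dX += dXc.cols(c0, c0 + D - 1);
    } else if (s > 0 && s < R) {
      dX.rows(0, R - 1 - s) += dXc.submat(s, c0, R - 1, c0 + D - 1);
    } else if (s < 0 && -s < R) {
      dX.rows(-s, R - 1) += dXc.submat(0, c0, R - 1 + s, c0 + D - 1);
    }
  }
}

struct Cfg {
  int D, H, K, L, base;
  bool quality;
};

static Cfg read_cfg(List config) {
  Cfg c;
  c.D = as<int>(config["embed_dim"]);
  c.H = as<int>(config["quality_hidden_dim"]);
  c.K = as<int>(config["kernel_width"]);
  c.L = as<int>(config["backbone_layers"]);
  c.base = as<int>(config["dilation_base"]);
  c.quality = as<bool>(config["quality_block"]);
  return c;
}

struct Caches {
  arma::mat A1, A2;            // quality block activations
  std::vector<arma::mat> xs;   // layer inputs (and final features)
  std::vector<arma::mat> Tg, G;
  arma::mat Hh;
  arma::vec pa;
};

static void forward_pass(List& params, const Cfg& cfg,
                         const IntegerVector& tokens, const arma::vec& qv,
                         const std::vector<int>& padrows, int B, bool keep,
                         Caches& cc) {
  const int R = tokens.size();
  arma::mat EMB = as_view(params["EMB"]);
  arma::mat X(R, cfg.D);
  for (int r = 0; r < R; ++r) X.row(r) = EMB.row(tokens[r] - 1);

  if (cfg.quality) {
    arma::mat w1 = as_view(params["q_w1"]), b1 = as_view(params["q_b1"]);
    arma::mat W2 = as_view(params["q_W2"]), b2 = as_view(params["q_b2"]);
    arma::mat W3 = as_view(params["q_W3"]), b3 = as_view(params["q_b3"]);
    arma::mat A1 = qv * w1.t();
    A1.each_row() += b1.t();
    relu_inplace(A1);
    arma::mat H2 = A1 * W2;
    H2.each_row() += b2.t();
    relu_inplace(H2);
    arma::mat A2 = H2 + A1;
    X += A2 * W3;
    X.each_row() += b3.t();
    if (keep) { cc.A1 = std::move(A1); cc.A2 = std::move(A2); }
  }
  zero_rows(X, padrows);

  arma::mat Xc;
  if (keep) { cc.xs.resize(cfg.L + 1); cc.Tg.resize(cfg.L); cc.G.resize(cfg.L); }
  int step = B;
  for (int l = 0; l < cfg.L; ++l) {
    if (keep) cc.xs[l] = X;
    conv_cols(X, cfg.K, step, Xc);
    arma::mat Wfg = as_view(params[std::string("Wfg_") + std::to_string(l + 1)]);
    arma::mat bf = as_view(params[std::string("bf_") + std::to_string(l + 1)]);
    arma::mat bg = as_view(params[std::string("bg_") + std::to_string(l + 1)]);
    arma::mat UV = Xc * Wfg;
    arma::mat Tg = UV.cols(0, cfg.D - 1);
    Tg.each_row() += bf.t();
    tanh_inplace(Tg);
    arma::mat G = UV.cols(cfg.D, 2 * cfg.D - 1);
    G.each_row() += bg.t();
    sigmoid_inplace(G);
    X += Tg % G;
    zero_rows(X, padrows);
    if (keep) { cc.Tg[l] = std::move(Tg); cc.G[l] = std::move(G); }
    step *= cfg.base;
  }
  if (keep) cc.xs[cfg.L] = X;

  arma::mat Wh1 = as_view(params["Wh1"]), bh1 = as_view(params["bh1"]);
  arma::mat Wh2 = as_view(params["Wh2"]), bh2 = as_view(params["bh2"]);
  arma::mat Hh = X * Wh1;
  Hh.each_row() += bh1.t();
  relu_inplace(Hh);
  arma::mat Z = Hh * Wh2;
  Z.each_row() += bh2.t();
  cc.pa = 1.0 / (1.0 + arma::exp(Z.col(1) - Z.col(0)));
  if (keep) cc.Hh = std::move(Hh);
  if (!keep) {
    // keep final features only when training
    cc.xs.clear();
  }
}

// Forward-only pass: per-position adapter probabilities for one batch.
// [[Rcpp::export(name = ".nc_forward_cpp")]]
NumericVector nc_forward_cpp(List params, List config, IntegerVector tokens,
                             NumericVector qv, int B) {
  Cfg cfg = read_cfg(config);
  const int R = tokens.size();
  std::vector<int> padrows;
  for (int r = 0; r < R; ++r) if (tokens[r] == PAD_ID) padrows.push_back(r);
  arma::vec q(qv.begin(), R, false, true);
  Caches cc;
  forward_pass(params, cfg, tokens, q, padrows, B, false, cc);
  return NumericVector(cc.pa.begin(), cc.pa.end());
}

// One fused training step: forward, loss, backward, Adam update (in place
// on params and the optimizer moments). Returns the batch loss.
// [[Rcpp::export(name = ".nc_train_step_cpp")]]
double nc_train_step_cpp(List params, List config, List mstate, List vstate,
                         int t, double lr, double beta1, double beta2,
                         IntegerVector tokens, NumericVector qv,
                         NumericVector labels, NumericVector wt, int B) {
  Cfg cfg = read_cfg(config);
  const int R = tokens.size();
  const double eps = 1e-7;
  std::vector<int> padrows;
  for (int r = 0; r < R; ++r) if (tokens[r] == PAD_ID) padrows.push_back(r);
  arma::vec q(qv.begin(), R, false, true);
  arma::vec y(labels.begin(), R, false, true);
  arma::vec w(wt.begin(), R, false, true);

  Caches cc;
  forward_pass(params, cfg, tokens, q, padrows, B, true, cc);

  double loss = 0.0;
  {
    const double* pp = cc.pa.memptr();
    const double* yy = y.memptr();
    const double* ww = w.memptr();
    for (int r = 0; r < R; ++r) {
      double pc = std::min(std::max(pp[r], eps), 1.0 - eps);
      loss -= ww[r] * (yy[r] * std::log(pc) + (1.0 - yy[r]) * std::log(1.0 - pc));
    }
  }

  std::map<std::string, arma::mat> gr;
  arma::vec g = w % (cc.pa - y);
  arma::mat dZ(R, 2);
  dZ.col(0) = g;
  dZ.col(1) = -g;

  arma::mat Wh1 = as_view(params["Wh1"]), Wh2 = as_view(params["Wh2"]);
  gr["Wh2"] = cc.Hh.t() * dZ;
  gr["bh2"] = arma::sum(dZ, 0).t();
  arma::mat dHh = dZ * Wh2.t();
  dHh %= arma::conv_to<arma::mat>::from(cc.Hh > 0);
  gr["Wh1"] = cc.xs[cfg.L].t() * dHh;
  gr["bh1"] = arma::sum(dHh, 0).t();
  arma::mat dX = dHh * Wh1.t();

  arma::mat Xc, dXc;
  int step = B;
  for (int l = 0; l < cfg.L - 1; ++l) step *= cfg.base;
  for (int l = cfg.L - 1; l >= 0; --l) {
    zero_rows(dX, padrows);
    const arma::mat& Tg = cc.Tg[l];
    const arma::mat& G = cc.G[l];
    arma::mat dU = dX % G % (1.0 - Tg % Tg);
    arma::mat dV = dX % Tg % G % (1.0 - G);
    std::string suf = std::to_string(l + 1);
    gr["bf_" + suf] = arma::sum(dU, 0).t();
    gr["bg_" + suf] = arma::sum(dV, 0).t();
    arma::mat dUV = arma::join_rows(dU, dV);
    conv_cols(cc.xs[l], cfg.K, step, Xc);
    gr["Wfg_" + suf] = Xc.t() * dUV;
    arma::mat Wfg = as_view(params["Wfg_" + suf]);
    dXc = dUV * Wfg.t();
    conv_fold(dXc, cfg.K, step, cfg.D, dX);
    step /= cfg.base;
  }
  zero_rows(dX, padrows);

  arma::mat dE(PAD_ID, cfg.D, arma::fill::zeros);
  for (int r = 0; r < R; ++r) dE.row(tokens[r] - 1) += dX.row(r);
  gr["EMB"] = dE;

  if (cfg.quality) {
    arma::mat W2 = as_view(params["q_W2"]), W3 = as_view(params["q_W3"]);
    gr["q_W3"] = cc.A2.t() * dX;
    gr["q_b3"] = arma::sum(dX, 0).t();
    arma::mat dA2 = dX * W3.t();
    arma::mat dH2 = dA2 % arma::conv_to<arma::mat>::from((cc.A2 - cc.A1) > 0);
    gr["q_W2"] = cc.A1.t() * dH2;
    gr["q_b2"] = arma::sum(dH2, 0).t();
    arma::mat dA1 = dH2 * W2.t() + dA2;
    dA1 %= arma::conv_to<arma::mat>::from(cc.A1 > 0);
    gr["q_w1"] = dA1.t() * q;
    gr["q_b1"] = arma::sum(dA1, 0).t();
  }

  // Adam with bias correction, updating params and moments in place
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  const double aeps = 1e-8;
  for (auto& kv : gr) {
    const std::string& nm = kv.first;
    arma::mat P = as_view(params[nm]);
    arma::mat M = as_view(mstate[nm]);
    arma::mat V = as_view(vstate[nm]);
    double* pp = P.memptr();
    double* mm = M.memptr();
    double* vv = V.memptr();
    const double* gg = kv.second.memptr();
    const arma::uword n = P.n_elem;
    for (arma::uword i = 0; i < n; ++i) {
      mm[i] = beta1 * mm[i] + (1.0 - beta1) * gg[i];
      vv[i] = beta2 * vv[i] + (1.0 - beta2) * gg[i] * gg[i];
      pp[i] -= lr * (mm[i] / c1) / (std::sqrt(vv[i] / c2) + aeps);
    }
  }
  return loss;
}
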