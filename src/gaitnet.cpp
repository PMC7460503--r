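// Compiled forward/backward passes and the mini-batch gradient-descent
// trainer for the gait-phase networks. Layouts mirror the R reference
// operations in R/layers.R exactly; tests cross-check the two routes.
//
// Flattened input layout (one row of X per example):
//   column a*L*S + s*L + r*cols + c  (all 0-based)
// = axis a, sub-window s, map row r, map column c.
// Conv patch vectors are channel-major, then row-major within the kernel.
// LSTM gate blocks are ordered (input, forget, candidate, output).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG_CLAMP = 1e-12;

enum ActKind { ACT_RELU = 0, ACT_TANH = 1 };

static int act_from_string(const std::string& s) {
  if (s == "relu") return ACT_RELU;
  if (s == "tanh") return ACT_TANH;
  Rcpp::stop("unknown LSTM activation '" + s + "' (use 'relu' or 'tanh')");
}

struct Cfg {
  int rows, cols, channels, S;
  int k1, F1, F2, F3;
  int H, fc1, fc2, ncls;
  double forget_bias, eps, slope, momentum;
  int act;
  bool use_skip, use_bn;
  // derived
  int L, span, m1, P1n, K1, K2, Dl, D1;
};

static Cfg cfg_from_list(const Rcpp::List& cl) {
  Cfg c;
  c.rows = cl["map_rows"]; c.cols = cl["map_cols"];
  c.channels = cl["channels"]; c.S = cl["n_sub"];
  Rcpp::IntegerVector filt = cl["conv_filters"];
  Rcpp::IntegerVector kern = cl["conv_kernels"];
  c.k1 = kern[0]; c.F1 = filt[0]; c.F2 = filt[1]; c.F3 = filt[2];
  c.H = cl["lstm_units"];
  Rcpp::IntegerVector fc = cl["fc_units"];
  c.fc1 = fc[0]; c.fc2 = fc[1];
  c.ncls = cl["n_classes"];
  c.forget_bias = cl["forget_bias"];
  c.eps = cl["bn_eps"];
  c.slope = cl["leaky_slope"];
  c.momentum = cl["bn_momentum"];
  c.act = act_from_string(Rcpp::as<std::string>(cl["lstm_activation"]));
  c.use_skip = cl["use_skip"];
  c.use_bn = cl["use_bn"];
  c.L = c.rows * c.cols;
  c.span = c.L * c.S;
  c.m1 = c.rows - c.k1 + 1;
  c.P1n = c.m1 * c.m1;
  c.K1 = c.channels * c.k1 * c.k1;
  c.K2 = c.P1n * c.F1;
  c.Dl = c.F2 + c.F3;
  c.D1 = c.use_skip ? (c.H + 3 * c.span) : c.H;
  return c;
}

// ---------------------------------------------------------------------
// batch normalization helpers (population variance over the batch)

struct BnCache { mat xhat; rowvec invstd, mu, var_; };

static mat bn_fwd_train(const mat& Z, const vec& g, const vec& be,
                        double eps, BnCache& cc) {
  const double n = (double)Z.n_rows;
  cc.mu = sum(Z, 0) / n;
  mat centered = Z.each_row() - cc.mu;
  cc.var_ = sum(square(centered), 0) / n;
  cc.invstd = 1.0 / sqrt(cc.var_ + eps);
  cc.xhat = centered.each_row() % cc.invstd;
  mat y = cc.xhat.each_row() % g.t();
  y.each_row() += be.t();
  return y;
}

static mat bn_fwd_infer(const mat& Z, const vec& g, const vec& be,
                        const vec& rm, const vec& rv, double eps) {
  rowvec invstd = 1.0 / sqrt(rv.t() + eps);
  mat xhat = (Z.each_row() - rm.t()).each_row() % invstd;
  mat y = xhat.each_row() % g.t();
  y.each_row() += be.t();
  return y;
}

static mat bn_bwd(const mat& dY, const BnCache& cc, const vec& g,
                  vec& dg, vec& dbe) {
  const double n = (double)dY.n_rows;
  dg = sum(dY % cc.xhat, 0).t();
  dbe = sum(dY, 0).t();
  rowvec sdY = sum(dY, 0);
  rowvec sdYx = sum(dY % cc.xhat, 0);
  mat dX = n * dY;
  dX.each_row() -= sdY;
  dX -= cc.xhat.each_row() % sdYx;
  dX.each_row() %= (g.t() % cc.invstd) / n;
  return dX;
}

// ---------------------------------------------------------------------
// LSTM helpers (batched, cached for BPTT)

struct LstmCache {
  cube I, F, G, O, C, Hc;  // m x H x S
  cube Hprev;              // m x H x (S+1), Hprev.slice(s) = h before step s
};

static inline double sig1(double x) { return 1.0 / (1.0 + std::exp(-x)); }
static inline double act1(double x, int k) {
  return k == ACT_RELU ? (x > 0.0 ? x : 0.0) : std::tanh(x);
}
// derivative from the activation output value
static inline double actd1(double y, int k) {
  return k == ACT_RELU ? (y > 0.0 ? 1.0 : 0.0) : 1.0 - y * y;
}

// Fused gate loops: the recurrence is the package's hot path, so the
// elementwise work runs over raw slice pointers in a single pass.
static mat lstm_fwd(const cube& U, const mat& Wx, const mat& Wh,
                    const vec& bl, double fb, int act, int H,
                    LstmCache* cc) {
  const int m = U.n_rows, S = U.n_slices;
  const int mH = m * H;
  mat h(m, H, fill::zeros), c(m, H, fill::zeros), cnew(m, H);
  if (cc) {
    cc->I.set_size(m, H, S); cc->F.set_size(m, H, S);
    cc->G.set_size(m, H, S); cc->O.set_size(m, H, S);
    cc->C.set_size(m, H, S); cc->Hc.set_size(m, H, S);
    cc->Hprev.set_size(m, H, S + 1);
    cc->Hprev.slice(0).zeros();
  }
  mat gates(m, 4 * H);
  for (int s = 0; s < S; ++s) {
    gates = U.slice(s) * Wx;
    gates += h * Wh;
    gates.each_row() += bl.t();
    const double* pi = gates.memptr();
    const double* pf = pi + mH;
    const double* pg = pf + mH;
    const double* po = pg + mH;
    double* pc = c.memptr();
    double* pcn = cnew.memptr();
    double* ph = h.memptr();
    double *ci = nullptr, *cf = nullptr, *cg = nullptr, *co = nullptr,
           *ccp = nullptr, *chc = nullptr;
    if (cc) {
      ci = cc->I.slice_memptr(s); cf = cc->F.slice_memptr(s);
      cg = cc->G.slice_memptr(s); co = cc->O.slice_memptr(s);
      ccp = cc->C.slice_memptr(s); chc = cc->Hc.slice_memptr(s);
    }
    for (int k = 0; k < mH; ++k) {
      const double gi = sig1(pi[k]);
      const double gf = sig1(pf[k] + fb);
      const double gg = act1(pg[k], act);
      const double go = sig1(po[k]);
      const double cv = gf * pc[k] + gi * gg;
      const double hc = act1(cv, act);
      pcn[k] = cv;
      ph[k] = go * hc;
      if (cc) {
        ci[k] = gi; cf[k] = gf; cg[k] = gg; co[k] = go;
        ccp[k] = cv; chc[k] = hc;
      }
    }
    c = cnew;
    if (cc) cc->Hprev.slice(s + 1) = h;
  }
  return h;
}

static void lstm_bwd(const cube& U, const mat& Wx, const mat& Wh,
                     const LstmCache& cc, const mat& dh_final, int act,
                     int H, mat& dWx, mat& dWh, vec& dbl, cube& dU,
                     bool need_dU) {
  const int m = U.n_rows, S = U.n_slices;
  const int mH = m * H;
  dWx.zeros(Wx.n_rows, Wx.n_cols);
  dWh.zeros(Wh.n_rows, Wh.n_cols);
  rowvec dbl_acc(4 * H, fill::zeros);
  if (need_dU) dU.set_size(m, U.n_cols, S);
  mat dh = dh_final;
  mat dc(m, H, fill::zeros);
  mat dG(m, 4 * H);
  for (int s = S - 1; s >= 0; --s) {
    const double* gi = cc.I.slice_memptr(s);
    const double* gf = cc.F.slice_memptr(s);
    const double* gg = cc.G.slice_memptr(s);
    const double* go = cc.O.slice_memptr(s);
    const double* hc = cc.Hc.slice_memptr(s);
    const double* cp = (s > 0) ? cc.C.slice_memptr(s - 1) : nullptr;
    double* pdh = dh.memptr();
    double* pdc = dc.memptr();
    double* di = dG.memptr();
    double* df = di + mH;
    double* dg = df + mH;
    double* dob = dg + mH;
    for (int k = 0; k < mH; ++k) {
      const double dhk = pdh[k];
      // for relu, actd1(hc) encodes c > 0; for tanh, 1 - hc^2
      const double dck = pdc[k] + dhk * go[k] * actd1(hc[k], act);
      const double cpv = cp ? cp[k] : 0.0;
      di[k] = dck * gg[k] * gi[k] * (1.0 - gi[k]);
      df[k] = dck * cpv * gf[k] * (1.0 - gf[k]);
      dg[k] = dck * gi[k] * actd1(gg[k], act);
      dob[k] = dhk * hc[k] * go[k] * (1.0 - go[k]);
      pdc[k] = dck * gf[k];  // gradient flowing to c_{s-1}
    }
    dWx += U.slice(s).t() * dG;
    dWh += cc.Hprev.slice(s).t() * dG;
    dbl_acc += sum(dG, 0);
    if (need_dU) dU.slice(s) = dG * Wx.t();
    dh = dG * Wh.t();
  }
  dbl = dbl_acc.t();
}

// ---------------------------------------------------------------------
// parameter containers

struct FmsParams {
  mat W1, W2, W3, Wx, Wh, Wf1, Wf2, Wf3;
  vec b1, b2, b3, bl, bf1, bf2, bf3;
  vec g1, be1, g2, be2, g3, be3, gf1, bef1, gf2, bef2;
  bool use_bn;
};

static FmsParams fms_from_list(const Rcpp::List& p, bool use_bn) {
  FmsParams q;
  q.W1 = Rcpp::as<mat>(p["W1"]); q.b1 = Rcpp::as<vec>(p["b1"]);
  q.W2 = Rcpp::as<mat>(p["W2"]); q.b2 = Rcpp::as<vec>(p["b2"]);
  q.W3 = Rcpp::as<mat>(p["W3"]); q.b3 = Rcpp::as<vec>(p["b3"]);
  q.Wx = Rcpp::as<mat>(p["Wx"]); q.Wh = Rcpp::as<mat>(p["Wh"]);
  q.bl = Rcpp::as<vec>(p["bl"]);
  q.Wf1 = Rcpp::as<mat>(p["Wf1"]); q.bf1 = Rcpp::as<vec>(p["bf1"]);
  q.Wf2 = Rcpp::as<mat>(p["Wf2"]); q.bf2 = Rcpp::as<vec>(p["bf2"]);
  q.Wf3 = Rcpp::as<mat>(p["Wf3"]); q.bf3 = Rcpp::as<vec>(p["bf3"]);
  q.use_bn = use_bn;
  if (use_bn) {
    q.g1 = Rcpp::as<vec>(p["g1"]); q.be1 = Rcpp::as<vec>(p["be1"]);
    q.g2 = Rcpp::as<vec>(p["g2"]); q.be2 = Rcpp::as<vec>(p["be2"]);
    q.g3 = Rcpp::as<vec>(p["g3"]); q.be3 = Rcpp::as<vec>(p["be3"]);
    q.gf1 = Rcpp::as<vec>(p["gf1"]); q.bef1 = Rcpp::as<vec>(p["bef1"]);
    q.gf2 = Rcpp::as<vec>(p["gf2"]); q.bef2 = Rcpp::as<vec>(p["bef2"]);
  }
  return q;
}

static Rcpp::List fms_to_list(const FmsParams& q) {
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("W1") = q.W1, Rcpp::Named("b1") = q.b1,
    Rcpp::Named("W2") = q.W2, Rcpp::Named("b2") = q.b2,
    Rcpp::Named("W3") = q.W3, Rcpp::Named("b3") = q.b3,
    Rcpp::Named("Wx") = q.Wx, Rcpp::Named("Wh") = q.Wh,
    Rcpp::Named("bl") = q.bl,
    Rcpp::Named("Wf1") = q.Wf1, Rcpp::Named("bf1") = q.bf1,
    Rcpp::Named("Wf2") = q.Wf2, Rcpp::Named("bf2") = q.bf2,
    Rcpp::Named("Wf3") = q.Wf3, Rcpp::Named("bf3") = q.bf3);
  if (q.use_bn) {
    out["g1"] = q.g1; out["be1"] = q.be1;
    out["g2"] = q.g2; out["be2"] = q.be2;
    out["g3"] = q.g3; out["be3"] = q.be3;
    out["gf1"] = q.gf1; out["bef1"] = q.bef1;
    out["gf2"] = q.gf2; out["bef2"] = q.bef2;
  }
  return out;
}

struct RStats { vec m1_, v1_, m2_, v2_, m3_, v3_, mf1_, vf1_, mf2_, vf2_; };

static RStats rstats_from_list(const Rcpp::List& s) {
  RStats r;
  r.m1_ = Rcpp::as<vec>(s["m1"]); r.v1_ = Rcpp::as<vec>(s["v1"]);
  r.m2_ = Rcpp::as<vec>(s["m2"]); r.v2_ = Rcpp::as<vec>(s["v2"]);
  r.m3_ = Rcpp::as<vec>(s["m3"]); r.v3_ = Rcpp::as<vec>(s["v3"]);
  r.mf1_ = Rcpp::as<vec>(s["mf1"]); r.vf1_ = Rcpp::as<vec>(s["vf1"]);
  r.mf2_ = Rcpp::as<vec>(s["mf2"]); r.vf2_ = Rcpp::as<vec>(s["vf2"]);
  return r;
}

static Rcpp::List rstats_to_list(const RStats& r) {
  return Rcpp::List::create(
    Rcpp::Named("m1") = r.m1_, Rcpp::Named("v1") = r.v1_,
    Rcpp::Named("m2") = r.m2_, Rcpp::Named("v2") = r.v2_,
    Rcpp::Named("m3") = r.m3_, Rcpp::Named("v3") = r.v3_,
    Rcpp::Named("mf1") = r.mf1_, Rcpp::Named("vf1") = r.vf1_,
    Rcpp::Named("mf2") = r.mf2_, Rcpp::Named("vf2") = r.vf2_);
}

// ---------------------------------------------------------------------
// patch gathering for the convolutional front end

static mat gather_p1(const mat& X, const Cfg& c) {
  const int m = X.n_rows;
  mat P1(m * c.S * c.P1n, c.K1);
  for (int s = 0; s < c.S; ++s) {
    for (int p = 0; p < c.P1n; ++p) {
      const int pr = p / c.m1, pc = p % c.m1;
      const int r0 = s * c.P1n * m + p * m;
      for (int a = 0; a < c.channels; ++a) {
        for (int kr = 0; kr < c.k1; ++kr) {
          for (int kc = 0; kc < c.k1; ++kc) {
            const int col = a * c.k1 * c.k1 + kr * c.k1 + kc;
            const int src = a * c.span + s * c.L +
                            (pr + kr) * c.cols + (pc + kc);
            P1.submat(r0, col, r0 + m - 1, col) = X.col(src);
          }
        }
      }
    }
  }
  return P1;
}

static mat gather_p2(const mat& H1, const Cfg& c, int m) {
  mat P2(m * c.S, c.K2);
  for (int s = 0; s < c.S; ++s) {
    for (int f = 0; f < c.F1; ++f) {
      for (int p = 0; p < c.P1n; ++p) {
        P2.submat(s * m, f * c.P1n + p, s * m + m - 1, f * c.P1n + p) =
          H1.submat(s * c.P1n * m + p * m, f,
                    s * c.P1n * m + (p + 1) * m - 1, f);
      }
    }
  }
  return P2;
}

static void scatter_p2(const mat& dP2, mat& dH1, const Cfg& c, int m) {
  for (int s = 0; s < c.S; ++s) {
    for (int f = 0; f < c.F1; ++f) {
      for (int p = 0; p < c.P1n; ++p) {
        dH1.submat(s * c.P1n * m + p * m, f,
                   s * c.P1n * m + (p + 1) * m - 1, f) =
          dP2.submat(s * m, f * c.P1n + p, s * m + m - 1, f * c.P1n + p);
      }
    }
  }
}

// ---------------------------------------------------------------------
// FMS-Net family: forward (train/infer) and backward

static mat leaky_fwd(const mat& z, double slope) {
  return z % (conv_to<mat>::from(z > 0.0) * (1.0 - slope) + slope);
}
static mat leaky_deriv(const mat& z, double slope) {
  return conv_to<mat>::from(z > 0.0) * (1.0 - slope) + slope;
}

static mat softmax_rows(const mat& Z) {
  mat E = exp(Z.each_col() - max(Z, 1));
  E.each_col() /= sum(E, 1);
  return E;
}

static double ce_loss(const mat& Q, const uvec& y) {
  double loss = 0.0;
  for (uword i = 0; i < y.n_elem; ++i) {
    loss += -std::log(std::max(Q(i, y(i)), LOG_CLAMP));
  }
  return loss / (double)y.n_elem;
}

// training-mode pass; fills grads and batch BN stats
static double fms_grad(const FmsParams& P, const mat& X, const uvec& y,
                       const Cfg& c, FmsParams& dP, RStats& bstats) {
  const int m = X.n_rows;
  // ---- forward
  mat P1 = gather_p1(X, c);
  mat Z1 = P1 * P.W1; Z1.each_row() += P.b1.t();
  BnCache c1, c2, c3, cf1, cf2;
  mat Y1 = c.use_bn ? bn_fwd_train(Z1, P.g1, P.be1, c.eps, c1) : Z1;
  mat H1 = clamp(Y1, 0.0, datum::inf);
  mat P2 = gather_p2(H1, c, m);
  mat Z2 = P2 * P.W2; Z2.each_row() += P.b2.t();
  mat Y2 = c.use_bn ? bn_fwd_train(Z2, P.g2, P.be2, c.eps, c2) : Z2;
  mat H2 = clamp(Y2, 0.0, datum::inf);
  mat Z3 = H2 * P.W3; Z3.each_row() += P.b3.t();
  mat Y3 = c.use_bn ? bn_fwd_train(Z3, P.g3, P.be3, c.eps, c3) : Z3;
  mat H3 = clamp(Y3, 0.0, datum::inf);
  cube U(m, c.Dl, c.S);
  for (int s = 0; s < c.S; ++s) {
    U.slice(s) = join_rows(H2.rows(s * m, s * m + m - 1),
                           H3.rows(s * m, s * m + m - 1));
  }
  LstmCache lc;
  mat olstm = lstm_fwd(U, P.Wx, P.Wh, P.bl, c.forget_bias, c.act, c.H, &lc);
  mat A0 = c.use_skip ? join_rows(olstm, X) : olstm;
  mat Zf1 = A0 * P.Wf1; Zf1.each_row() += P.bf1.t();
  mat Yf1 = c.use_bn ? bn_fwd_train(Zf1, P.gf1, P.bef1, c.eps, cf1) : Zf1;
  mat A1 = leaky_fwd(Yf1, c.slope);
  mat Zf2 = A1 * P.Wf2; Zf2.each_row() += P.bf2.t();
  mat Yf2 = c.use_bn ? bn_fwd_train(Zf2, P.gf2, P.bef2, c.eps, cf2) : Zf2;
  mat A2 = leaky_fwd(Yf2, c.slope);
  mat logits = A2 * P.Wf3; logits.each_row() += P.bf3.t();
  mat Q = softmax_rows(logits);
  double loss = ce_loss(Q, y);
  if (c.use_bn) {
    bstats.m1_ = c1.mu.t(); bstats.v1_ = c1.var_.t();
    bstats.m2_ = c2.mu.t(); bstats.v2_ = c2.var_.t();
    bstats.m3_ = c3.mu.t(); bstats.v3_ = c3.var_.t();
    bstats.mf1_ = cf1.mu.t(); bstats.vf1_ = cf1.var_.t();
    bstats.mf2_ = cf2.mu.t(); bstats.vf2_ = cf2.var_.t();
  }
  // ---- backward
  dP.use_bn = c.use_bn;
  mat dZf3 = Q;
  for (uword i = 0; i < y.n_elem; ++i) dZf3(i, y(i)) -= 1.0;
  dZf3 /= (double)m;
  dP.Wf3 = A2.t() * dZf3; dP.bf3 = sum(dZf3, 0).t();
  mat dA2 = dZf3 * P.Wf3.t();
  mat dYf2 = dA2 % leaky_deriv(Yf2, c.slope);
  mat dZf2 = c.use_bn ? bn_bwd(dYf2, cf2, P.gf2, dP.gf2, dP.bef2) : dYf2;
  dP.Wf2 = A1.t() * dZf2; dP.bf2 = sum(dZf2, 0).t();
  mat dA1 = dZf2 * P.Wf2.t();
  mat dYf1 = dA1 % leaky_deriv(Yf1, c.slope);
  mat dZf1 = c.use_bn ? bn_bwd(dYf1, cf1, P.gf1, dP.gf1, dP.bef1) : dYf1;
  dP.Wf1 = A0.t() * dZf1; dP.bf1 = sum(dZf1, 0).t();
  mat dA0 = dZf1 * P.Wf1.t();
  mat dh = dA0.cols(0, c.H - 1);  // skip path carries data, not parameters
  cube dU;
  lstm_bwd(U, P.Wx, P.Wh, lc, dh, c.act, c.H, dP.Wx, dP.Wh, dP.bl, dU,
           true);
  mat dH2(m * c.S, c.F2), dH3(m * c.S, c.F3);
  for (int s = 0; s < c.S; ++s) {
    dH2.rows(s * m, s * m + m - 1) = dU.slice(s).cols(0, c.F2 - 1);
    dH3.rows(s * m, s * m + m - 1) = dU.slice(s).cols(c.F2, c.Dl - 1);
  }
  mat dY3 = dH3 % conv_to<mat>::from(Y3 > 0.0);
  mat dZ3 = c.use_bn ? bn_bwd(dY3, c3, P.g3, dP.g3, dP.be3) : dY3;
  dP.W3 = H2.t() * dZ3; dP.b3 = sum(dZ3, 0).t();
  dH2 += dZ3 * P.W3.t();
  mat dY2 = dH2 % conv_to<mat>::from(Y2 > 0.0);
  mat dZ2 = c.use_bn ? bn_bwd(dY2, c2, P.g2, dP.g2, dP.be2) : dY2;
  dP.W2 = P2.t() * dZ2; dP.b2 = sum(dZ2, 0).t();
  mat dP2m = dZ2 * P.W2.t();
  mat dH1(H1.n_rows, c.F1);
  scatter_p2(dP2m, dH1, c, m);
  mat dY1 = dH1 % conv_to<mat>::from(Y1 > 0.0);
  mat dZ1 = c.use_bn ? bn_bwd(dY1, c1, P.g1, dP.g1, dP.be1) : dY1;
  dP.W1 = P1.t() * dZ1; dP.b1 = sum(dZ1, 0).t();
  return loss;
}

// inference-mode probabilities
static mat fms_prob(const FmsParams& P, const RStats& r, const mat& X,
                    const Cfg& c) {
  const int m = X.n_rows;
  mat P1 = gather_p1(X, c);
  mat Z1 = P1 * P.W1; Z1.each_row() += P.b1.t();
  if (c.use_bn) Z1 = bn_fwd_infer(Z1, P.g1, P.be1, r.m1_, r.v1_, c.eps);
  mat H1 = clamp(Z1, 0.0, datum::inf);
  mat P2 = gather_p2(H1, c, m);
  mat Z2 = P2 * P.W2; Z2.each_row() += P.b2.t();
  if (c.use_bn) Z2 = bn_fwd_infer(Z2, P.g2, P.be2, r.m2_, r.v2_, c.eps);
  mat H2 = clamp(Z2, 0.0, datum::inf);
  mat Z3 = H2 * P.W3; Z3.each_row() += P.b3.t();
  if (c.use_bn) Z3 = bn_fwd_infer(Z3, P.g3, P.be3, r.m3_, r.v3_, c.eps);
  mat H3 = clamp(Z3, 0.0, datum::inf);
  cube U(m, c.Dl, c.S);
  for (int s = 0; s < c.S; ++s) {
    U.slice(s) = join_rows(H2.rows(s * m, s * m + m - 1),
                           H3.rows(s * m, s * m + m - 1));
  }
  mat olstm = lstm_fwd(U, P.Wx, P.Wh, P.bl, c.forget_bias, c.act, c.H,
                       nullptr);
  mat A0 = c.use_skip ? join_rows(olstm, X) : olstm;
  mat Zf1 = A0 * P.Wf1; Zf1.each_row() += P.bf1.t();
  if (c.use_bn) Zf1 = bn_fwd_infer(Zf1, P.gf1, P.bef1, r.mf1_, r.vf1_, c.eps);
  mat A1 = leaky_fwd(Zf1, c.slope);
  mat Zf2 = A1 * P.Wf2; Zf2.each_row() += P.bf2.t();
  if (c.use_bn) Zf2 = bn_fwd_infer(Zf2, P.gf2, P.bef2, r.mf2_, r.vf2_, c.eps);
  mat A2 = leaky_fwd(Zf2, c.slope);
  mat logits = A2 * P.Wf3; logits.each_row() += P.bf3.t();
  return softmax_rows(logits);
}

// ---------------------------------------------------------------------
// plain LSTM variant: raw 3-channel sequence -> LSTM -> FC -> FC

struct LstmVarParams { mat Wx, Wh, Wf2, Wf3; vec bl, bf2, bf3; };

static LstmVarParams lvp_from_list(const Rcpp::List& p) {
  LstmVarParams q;
  q.Wx = Rcpp::as<mat>(p["Wx"]); q.Wh = Rcpp::as<mat>(p["Wh"]);
  q.bl = Rcpp::as<vec>(p["bl"]);
  q.Wf2 = Rcpp::as<mat>(p["Wf2"]); q.bf2 = Rcpp::as<vec>(p["bf2"]);
  q.Wf3 = Rcpp::as<mat>(p["Wf3"]); q.bf3 = Rcpp::as<vec>(p["bf3"]);
  return q;
}

static Rcpp::List lvp_to_list(const LstmVarParams& q) {
  return Rcpp::List::create(
    Rcpp::Named("Wx") = q.Wx, Rcpp::Named("Wh") = q.Wh,
    Rcpp::Named("bl") = q.bl,
    Rcpp::Named("Wf2") = q.Wf2, Rcpp::Named("bf2") = q.bf2,
    Rcpp::Named("Wf3") = q.Wf3, Rcpp::Named("bf3") = q.bf3);
}

static cube seq_from_x(const mat& X, const Cfg& c) {
  const int m = X.n_rows, Tn = c.span;
  cube U(m, c.channels, Tn);
  for (int t = 0; t < Tn; ++t) {
    for (int a = 0; a < c.channels; ++a) {
      U.slice(t).col(a) = X.col(a * Tn + t);
    }
  }
  return U;
}

static double lstmvar_grad(const LstmVarParams& P, const mat& X,
                           const uvec& y, const Cfg& c, LstmVarParams& dP) {
  const int m = X.n_rows;
  cube U = seq_from_x(X, c);
  LstmCache lc;
  mat h = lstm_fwd(U, P.Wx, P.Wh, P.bl, c.forget_bias, c.act, c.H, &lc);
  mat Zf2 = h * P.Wf2; Zf2.each_row() += P.bf2.t();
  mat A2 = leaky_fwd(Zf2, c.slope);
  mat logits = A2 * P.Wf3; logits.each_row() += P.bf3.t();
  mat Q = softmax_rows(logits);
  double loss = ce_loss(Q, y);
  mat dZf3 = Q;
  for (uword i = 0; i < y.n_elem; ++i) dZf3(i, y(i)) -= 1.0;
  dZf3 /= (double)m;
  dP.Wf3 = A2.t() * dZf3; dP.bf3 = sum(dZf3, 0).t();
  mat dA2 = dZf3 * P.Wf3.t();
  mat dZf2 = dA2 % leaky_deriv(Zf2, c.slope);
  dP.Wf2 = h.t() * dZf2; dP.bf2 = sum(dZf2, 0).t();
  mat dh = dZf2 * P.Wf2.t();
  cube dU;
  lstm_bwd(U, P.Wx, P.Wh, lc, dh, c.act, c.H, dP.Wx, dP.Wh, dP.bl, dU,
           false);
  return loss;
}

static mat lstmvar_prob(const LstmVarParams& P, const mat& X, const Cfg& c) {
  cube U = seq_from_x(X, c);
  mat h = lstm_fwd(U, P.Wx, P.Wh, P.bl, c.forget_bias, c.act, c.H, nullptr);
  mat Zf2 = h * P.Wf2; Zf2.each_row() += P.bf2.t();
  mat A2 = leaky_fwd(Zf2, c.slope);
  mat logits = A2 * P.Wf3; logits.each_row() += P.bf3.t();
  return softmax_rows(logits);
}

// ---------------------------------------------------------------------
// gradient clipping and SGD updates

template <typename T>
static double sq_norm(const T& x) { return accu(square(x)); }

static double fms_grad_norm(const FmsParams& g) {
  double s = sq_norm(g.W1) + sq_norm(g.b1) + sq_norm(g.W2) + sq_norm(g.b2) +
             sq_norm(g.W3) + sq_norm(g.b3) + sq_norm(g.Wx) + sq_norm(g.Wh) +
             sq_norm(g.bl) + sq_norm(g.Wf1) + sq_norm(g.bf1) +
             sq_norm(g.Wf2) + sq_norm(g.bf2) + sq_norm(g.Wf3) +
             sq_norm(g.bf3);
  if (g.use_bn) {
    s += sq_norm(g.g1) + sq_norm(g.be1) + sq_norm(g.g2) + sq_norm(g.be2) +
         sq_norm(g.g3) + sq_norm(g.be3) + sq_norm(g.gf1) + sq_norm(g.bef1) +
         sq_norm(g.gf2) + sq_norm(g.bef2);
  }
  return std::sqrt(s);
}

static void fms_sgd(FmsParams& P, const FmsParams& g, double step) {
  P.W1 -= step * g.W1; P.b1 -= step * g.b1;
  P.W2 -= step * g.W2; P.b2 -= step * g.b2;
  P.W3 -= step * g.W3; P.b3 -= step * g.b3;
  P.Wx -= step * g.Wx; P.Wh -= step * g.Wh; P.bl -= step * g.bl;
  P.Wf1 -= step * g.Wf1; P.bf1 -= step * g.bf1;
  P.Wf2 -= step * g.Wf2; P.bf2 -= step * g.bf2;
  P.Wf3 -= step * g.Wf3; P.bf3 -= step * g.bf3;
  if (P.use_bn) {
    P.g1 -= step * g.g1; P.be1 -= step * g.be1;
    P.g2 -= step * g.g2; P.be2 -= step * g.be2;
    P.g3 -= step * g.g3; P.be3 -= step * g.be3;
    P.gf1 -= step * g.gf1; P.bef1 -= step * g.bef1;
    P.gf2 -= step * g.gf2; P.bef2 -= step * g.bef2;
  }
}

static double lvp_grad_norm(const LstmVarParams& g) {
  return std::sqrt(sq_norm(g.Wx) + sq_norm(g.Wh) + sq_norm(g.bl) +
                   sq_norm(g.Wf2) + sq_norm(g.bf2) + sq_norm(g.Wf3) +
                   sq_norm(g.bf3));
}

static void lvp_sgd(LstmVarParams& P, const LstmVarParams& g, double step) {
  P.Wx -= step * g.Wx; P.Wh -= step * g.Wh; P.bl -= step * g.bl;
  P.Wf2 -= step * g.Wf2; P.bf2 -= step * g.bf2;
  P.Wf3 -= step * g.Wf3; P.bf3 -= step * g.bf3;
}

static uvec draw_batch(int N, int batch) {
  if (batch >= N) return regspace<uvec>(0, N - 1);
  Rcpp::IntegerVector idx = Rcpp::sample(N, batch, false);  // R's RNG
  uvec out(batch);
  for (int i = 0; i < batch; ++i) out(i) = idx[i] - 1;
  return out;
}

static void bn_running_update(vec& rm, vec& rv, const vec& mu, const vec& v,
                              double mom) {
  rm = mom * rm + (1.0 - mom) * mu;
  rv = mom * rv + (1.0 - mom) * v;
}

// ---------------------------------------------------------------------
// exported interface

// [[Rcpp::export]]
Rcpp::List cpp_fms_grad(const Rcpp::List& params, const arma::mat& X,
                        const arma::uvec& y, const Rcpp::List& cfg) {
  Cfg c = cfg_from_list(cfg);
  FmsParams P = fms_from_list(params, c.use_bn);
  FmsParams dP; RStats bs;
  double loss = fms_grad(P, X, y, c, dP, bs);
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("grads") = fms_to_list(dP));
  if (c.use_bn) out["batch_stats"] = rstats_to_list(bs);
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_fms_prob(const Rcpp::List& params, const Rcpp::List& rstats,
                       const arma::mat& X, const Rcpp::List& cfg) {
  Cfg c = cfg_from_list(cfg);
  FmsParams P = fms_from_list(params, c.use_bn);
  RStats r;
  if (c.use_bn) r = rstats_from_list(rstats);
  return fms_prob(P, r, X, c);
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_grad(const Rcpp::List& params, const arma::mat& X,
                         const arma::uvec& y, const Rcpp::List& cfg) {
  Cfg c = cfg_from_list(cfg);
  LstmVarParams P = lvp_from_list(params);
  LstmVarParams dP;
  double loss = lstmvar_grad(P, X, y, c, dP);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = lvp_to_list(dP));
}

// [[Rcpp::export]]
arma::mat cpp_lstm_prob(const Rcpp::List& params, const arma::mat& X,
                        const Rcpp::List& cfg) {
  Cfg c = cfg_from_list(cfg);
  LstmVarParams P = lvp_from_list(params);
  return lstmvar_prob(P, X, c);
}

// [[Rcpp::export]]
Rcpp::List cpp_train_fms(const Rcpp::List& params, const Rcpp::List& rstats,
                         const arma::mat& X, const arma::uvec& y,
                         const Rcpp::List& cfg, int iterations, int batch,
                         double lr, double clip, int log_every) {
  Cfg c = cfg_from_list(cfg);
  FmsParams P = fms_from_list(params, c.use_bn);
  RStats r;
  if (c.use_bn) r = rstats_from_list(rstats);
  const int N = X.n_rows;
  std::vector<double> hist;
  for (int it = 0; it < iterations; ++it) {
    uvec idx = draw_batch(N, batch);
    mat Xb = X.rows(idx);
    uvec yb = y.elem(idx);
    FmsParams dP; RStats bs;
    double loss = fms_grad(P, Xb, yb, c, dP, bs);
    if (!std::isfinite(loss)) {
      Rcpp::stop("training diverged to a non-finite loss at iteration %d; "
                 "try a lower learning rate or the tanh LSTM activation",
                 it + 1);
    }
    if (it % log_every == 0) hist.push_back(loss);
    double step = lr;
    if (clip > 0) {
      double gn = fms_grad_norm(dP);
      if (gn > clip) step = lr * clip / gn;
    }
    fms_sgd(P, dP, step);
    if (c.use_bn) {
      bn_running_update(r.m1_, r.v1_, bs.m1_, bs.v1_, c.momentum);
      bn_running_update(r.m2_, r.v2_, bs.m2_, bs.v2_, c.momentum);
      bn_running_update(r.m3_, r.v3_, bs.m3_, bs.v3_, c.momentum);
      bn_running_update(r.mf1_, r.vf1_, bs.mf1_, bs.vf1_, c.momentum);
      bn_running_update(r.mf2_, r.vf2_, bs.mf2_, bs.vf2_, c.momentum);
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("params") = fms_to_list(P),
    Rcpp::Named("loss_history") = hist);
  if (c.use_bn) out["running_stats"] = rstats_to_list(r);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_train_lstm(const Rcpp::List& params, const arma::mat& X,
                          const arma::uvec& y, const Rcpp::List& cfg,
                          int iterations, int batch, double lr, double clip,
                          int log_every) {
  Cfg c = cfg_from_list(cfg);
  LstmVarParams P = lvp_from_list(params);
  const int N = X.n_rows;
  std::vector<double> hist;
  for (int it = 0; it < iterations; ++it) {
    uvec idx = draw_batch(N, batch);
    mat Xb = X.rows(idx);
    uvec yb = y.elem(idx);
    LstmVarParams dP;
    double loss = lstmvar_grad(P, Xb, yb, c, dP);
    if (!std::isfinite(loss)) {
      Rcpp::stop("training diverged to a non-finite loss at iteration %d; "
                 "try a lower learning rate or the tanh LSTM activation",
                 it + 1);
    }
    if (it % log_every == 0) hist.push_back(loss);
    double step = lr;
    if (clip > 0) {
      double gn = lvp_grad_norm(dP);
      if (gn > clip) step = lr * clip / gn;
    }
    lvp_sgd(P, dP, step);
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = lvp_to_list(P),
                            Rcpp::Named("loss_history") = hist);
}
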