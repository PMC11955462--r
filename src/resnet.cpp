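// Residual CNN for 224x224 RGB patches, written directly against
// RcppArmadillo (no deep-learning framework exists in this R stack).
//
// Architecture (configurable): 7x7/2 stem conv + BN + ReLU + 3x3/2 max
// pool, then `stages` stages of `blocks` basic residual blocks (two 3x3
// convs with BN, identity skip; 1x1/2 projection at each stage transition
// after the first), global average pooling and a linear head.
//
// Data layout: a batch is an arma::fmat with one image per column; within
// a column, pixel (i, j) of channel c sits at index i + H*j + H*W*c,
// which matches the column-major layout of an R array dim c(H, W, C).
// Conv weights arrive from R as arrays dim c(kh, kw, cin, cout).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

static const float BN_EPS = 1e-5f;
static const float BN_MOM = 0.1f;   // running-stat update rate

// ---------------------------------------------------------------- layers

struct Conv {
  std::string name;
  int kh, kw, stride, pad, cin, cout, hin, win, hout, wout;
  fmat W, dW, vW;   // (cout, cin*kh*kw)
  bool frozen = false;
  void shape(const std::string& nm, int kh_, int kw_, int st, int pd,
             int ci, int co, int hi, int wi) {
    name = nm; kh = kh_; kw = kw_; stride = st; pad = pd;
    cin = ci; cout = co; hin = hi; win = wi;
    hout = (hi + 2 * pd - kh_) / st + 1;
    wout = (wi + 2 * pd - kw_) / st + 1;
  }
};

struct BN {
  std::string name;
  int C = 0, HW = 0;
  fvec gamma, beta, rm, rv, dgamma, dbeta, vgamma, vbeta, mean_, invstd_;
  fmat xhat;        // cached normalized activations (train mode)
  bool frozen = false;
  void shape(const std::string& nm, int C_, int HW_) { name = nm; C = C_; HW = HW_; }
};

struct Block {
  int stage = 0;
  bool down = false;
  Conv c1, c2, dc;
  BN b1, b2, dbn;
  fmat in, a1, out; // forward caches
};

struct Net {
  int S, B, W0, ncls, d_in;
  Conv conv1; BN bn1;
  fmat a1;                       // stem output after ReLU
  int ph, pw;                    // pooled spatial dims
  arma::Mat<arma::uword> pidx;   // max-pool argmax (flat per-image index)
  std::vector<Block> blocks;
  fmat fcW, fcdW, fcvW;
  fvec fcb, fcdb, fcvb;
  bool fc_frozen = false;
  fmat feat;                     // GAP output (Clast, N)
  const fmat* xbatch = nullptr;  // input of current batch (for stem backward)
  int hlast, wlast, clast;
};

// ------------------------------------------------------------ conv cores

static void im2col(const float* in, const Conv& L, fmat& col) {
  const int H = L.hin, OH = L.hout, OW = L.wout;
  col.zeros();
  for (int c = 0; c < L.cin; ++c)
    for (int ki = 0; ki < L.kh; ++ki)
      for (int kj = 0; kj < L.kw; ++kj) {
        const int r = (c * L.kh + ki) * L.kw + kj;
        for (int oj = 0; oj < OW; ++oj) {
          const int jj = oj * L.stride - L.pad + kj;
          if (jj < 0 || jj >= L.win) continue;
          const float* src = in + H * jj + H * L.win * c;
          for (int oi = 0; oi < OH; ++oi) {
            const int ii = oi * L.stride - L.pad + ki;
            if (ii < 0 || ii >= H) continue;
            col(r, oi + OH * oj) = src[ii];
          }
        }
      }
}

static void col2im_add(const fmat& dcol, const Conv& L, float* din) {
  const int H = L.hin, OH = L.hout, OW = L.wout;
  for (int c = 0; c < L.cin; ++c)
    for (int ki = 0; ki < L.kh; ++ki)
      for (int kj = 0; kj < L.kw; ++kj) {
        const int r = (c * L.kh + ki) * L.kw + kj;
        for (int oj = 0; oj < OW; ++oj) {
          const int jj = oj * L.stride - L.pad + kj;
          if (jj < 0 || jj >= L.win) continue;
          float* dst = din + H * jj + H * L.win * c;
          for (int oi = 0; oi < OH; ++oi) {
            const int ii = oi * L.stride - L.pad + ki;
            if (ii < 0 || ii >= H) continue;
            dst[ii] += dcol(r, oi + OH * oj);
          }
        }
      }
}

static void conv_forward(const Conv& L, const fmat& in, fmat& out) {
  const int N = in.n_cols, ohow = L.hout * L.wout;
  out.set_size(ohow * L.cout, N);
  fmat col(L.cin * L.kh * L.kw, ohow);
  for (int n = 0; n < N; ++n) {
    im2col(in.colptr(n), L, col);
    fmat om = L.W * col;            // (cout, ohow)
    float* op = out.colptr(n);
    for (int o = 0; o < L.cout; ++o)
      for (int p = 0; p < ohow; ++p) op[p + ohow * o] = om(o, p);
  }
}

static void conv_backward(Conv& L, const fmat& in, const fmat& dout,
                          fmat* din) {
  const int N = in.n_cols, ohow = L.hout * L.wout;
  fmat col(L.cin * L.kh * L.kw, ohow);
  fmat dom(L.cout, ohow);
  for (int n = 0; n < N; ++n) {
    const float* dp = dout.colptr(n);
    for (int o = 0; o < L.cout; ++o)
      for (int p = 0; p < ohow; ++p) dom(o, p) = dp[p + ohow * o];
    im2col(in.colptr(n), L, col);
    L.dW += dom * col.t();
    if (din) {
      fmat dcol = L.W.t() * dom;
      col2im_add(dcol, L, din->colptr(n));
    }
  }
}

// --------------------------------------------------------------- bn/relu

static void bn_forward(BN& L, fmat& A, bool train) {
  const int N = A.n_cols, HW = L.HW;
  if (train) {
    L.xhat.set_size(A.n_rows, N);
    L.mean_.set_size(L.C); L.invstd_.set_size(L.C);
    const double m = (double)HW * N;
    for (int c = 0; c < L.C; ++c) {
      auto sub = A.rows(c * HW, (c + 1) * HW - 1);
      const float mu = arma::accu(sub) / m;
      fmat cent = sub - mu;
      const float var = arma::accu(arma::square(cent)) / m;
      const float is = 1.0f / std::sqrt(var + BN_EPS);
      L.xhat.rows(c * HW, (c + 1) * HW - 1) = cent * is;
      sub = L.gamma[c] * L.xhat.rows(c * HW, (c + 1) * HW - 1) + L.beta[c];
      L.mean_[c] = mu; L.invstd_[c] = is;
      if (!L.frozen) {
        L.rm[c] = (1 - BN_MOM) * L.rm[c] + BN_MOM * mu;
        const float uvar = (m > 1) ? var * m / (m - 1) : var;
        L.rv[c] = (1 - BN_MOM) * L.rv[c] + BN_MOM * uvar;
      }
    }
  } else {
    for (int c = 0; c < L.C; ++c) {
      auto sub = A.rows(c * HW, (c + 1) * HW - 1);
      const float is = 1.0f / std::sqrt(L.rv[c] + BN_EPS);
      sub = L.gamma[c] * is * (sub - L.rm[c]) + L.beta[c];
    }
  }
}

static void bn_backward(BN& L, fmat& D, bool train) {
  const int N = D.n_cols, HW = L.HW;
  if (train) {
    const double m = (double)HW * N;
    for (int c = 0; c < L.C; ++c) {
      auto d = D.rows(c * HW, (c + 1) * HW - 1);
      auto xh = L.xhat.rows(c * HW, (c + 1) * HW - 1);
      const float db = arma::accu(d);
      const float dg = arma::accu(d % xh);
      L.dbeta[c] += db; L.dgamma[c] += dg;
      d = (L.gamma[c] * L.invstd_[c]) * (d - db / m - xh * (dg / m));
    }
  } else {
    for (int c = 0; c < L.C; ++c)
      D.rows(c * HW, (c + 1) * HW - 1) *=
        L.gamma[c] / std::sqrt(L.rv[c] + BN_EPS);
  }
}

static inline void relu_(fmat& A) {
  A.transform([](float v) { return v > 0 ? v : 0.0f; });
}
// gradient masked by cached post-ReLU activations
static inline void relu_mask_(fmat& D, const fmat& act) {
  float* d = D.memptr(); const float* a = act.memptr();
  const arma::uword n = D.n_elem;
  for (arma::uword i = 0; i < n; ++i) if (a[i] <= 0) d[i] = 0;
}

// ------------------------------------------------------------- max pool

static void pool_forward(Net& net, const fmat& in, fmat& out) {
  const int C = net.conv1.cout, H = net.conv1.hout, W = net.conv1.wout;
  const int OH = (H + 2 - 3) / 2 + 1, OW = (W + 2 - 3) / 2 + 1;
  net.ph = OH; net.pw = OW;
  const int N = in.n_cols;
  out.set_size(OH * OW * C, N);
  net.pidx.set_size(OH * OW * C, N);
  for (int n = 0; n < N; ++n) {
    const float* src = in.colptr(n);
    float* dst = out.colptr(n);
    arma::uword* ix = net.pidx.colptr(n);
    for (int c = 0; c < C; ++c) {
      const float* plane = src + H * W * c;
      for (int oj = 0; oj < OW; ++oj)
        for (int oi = 0; oi < OH; ++oi) {
          float best = -1e30f; arma::uword bi = 0;
          for (int kj = 0; kj < 3; ++kj) {
            const int jj = oj * 2 - 1 + kj;
            if (jj < 0 || jj >= W) continue;
            for (int ki = 0; ki < 3; ++ki) {
              const int ii = oi * 2 - 1 + ki;
              if (ii < 0 || ii >= H) continue;
              const float v = plane[ii + H * jj];
              if (v > best) { best = v; bi = ii + H * jj + H * W * c; }
            }
          }
          dst[oi + OH * oj + OH * OW * c] = best;
          ix[oi + OH * oj + OH * OW * c] = bi;
        }
    }
  }
}

static void pool_backward(const Net& net, const fmat& dout, fmat& din) {
  din.zeros(net.a1.n_rows, dout.n_cols);
  for (arma::uword n = 0; n < dout.n_cols; ++n) {
    const float* dp = dout.colptr(n);
    float* dd = din.colptr(n);
    const arma::uword* ix = net.pidx.colptr(n);
    for (arma::uword p = 0; p < dout.n_rows; ++p) dd[ix[p]] += dp[p];
  }
}

// ------------------------------------------------------- (de)serializing

static fmat conv_w_in(const NumericVector& a, int kh, int kw, int ci, int co) {
  fmat W(co, ci * kh * kw);
  for (int o = 0; o < co; ++o)
    for (int c = 0; c < ci; ++c)
      for (int ki = 0; ki < kh; ++ki)
        for (int kj = 0; kj < kw; ++kj)
          W(o, (c * kh + ki) * kw + kj) =
            (float)a[ki + kh * (kj + (R_xlen_t)kw * (c + (R_xlen_t)ci * o))];
  return W;
}

static NumericVector conv_w_out(const fmat& W, int kh, int kw, int ci, int co) {
  NumericVector a(kh * (R_xlen_t)kw * ci * co);
  for (int o = 0; o < co; ++o)
    for (int c = 0; c < ci; ++c)
      for (int ki = 0; ki < kh; ++ki)
        for (int kj = 0; kj < kw; ++kj)
          a[ki + kh * (kj + (R_xlen_t)kw * (c + (R_xlen_t)ci * o))] =
            W(o, (c * kh + ki) * kw + kj);
  a.attr("dim") = IntegerVector::create(kh, kw, ci, co);
  return a;
}

static fvec vec_in(const NumericVector& v) {
  fvec out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

static NumericVector vec_out(const fvec& v) {
  NumericVector out(v.n_elem);
  for (arma::uword i = 0; i < v.n_elem; ++i) out[i] = v[i];
  return out;
}

static void bn_in(BN& L, const List& params, const std::string& prefix) {
  L.gamma = vec_in(params[prefix + ".gamma"]);
  L.beta  = vec_in(params[prefix + ".beta"]);
  L.rm    = vec_in(params[prefix + ".rm"]);
  L.rv    = vec_in(params[prefix + ".rv"]);
}

static Net build_net(const List& params, const List& config) {
  Net net;
  net.S = as<int>(config["stages"]);
  net.B = as<int>(config["blocks_per_stage"]);
  net.W0 = as<int>(config["base_width"]);
  net.ncls = as<int>(config["n_classes"]);
  net.d_in = 3 * 224 * 224;

  net.conv1.shape("conv1", 7, 7, 2, 3, 3, net.W0, 224, 224);
  net.conv1.W = conv_w_in(params["conv1.w"], 7, 7, 3, net.W0);
  net.bn1.shape("bn1", net.W0, net.conv1.hout * net.conv1.wout);
  bn_in(net.bn1, params, "bn1");

  int h = (net.conv1.hout + 2 - 3) / 2 + 1;  // after max pool
  int w = (net.conv1.wout + 2 - 3) / 2 + 1;
  int cin = net.W0;
  for (int s = 1; s <= net.S; ++s) {
    const int cout = net.W0 << (s - 1);
    for (int b = 1; b <= net.B; ++b) {
      Block blk;
      blk.stage = s;
      const bool first = (b == 1);
      const int stride = (s > 1 && first) ? 2 : 1;
      blk.down = (stride != 1 || cin != cout);
      char buf[64];
      snprintf(buf, sizeof(buf), "s%d.b%d", s, b);
      const std::string px(buf);
      blk.c1.shape(px + ".conv1", 3, 3, stride, 1, cin, cout, h, w);
      blk.c1.W = conv_w_in(params[px + ".conv1.w"], 3, 3, cin, cout);
      blk.b1.shape(px + ".bn1", cout, blk.c1.hout * blk.c1.wout);
      bn_in(blk.b1, params, px + ".bn1");
      blk.c2.shape(px + ".conv2", 3, 3, 1, 1, cout, cout,
                   blk.c1.hout, blk.c1.wout);
      blk.c2.W = conv_w_in(params[px + ".conv2.w"], 3, 3, cout, cout);
      blk.b2.shape(px + ".bn2", cout, blk.c2.hout * blk.c2.wout);
      bn_in(blk.b2, params, px + ".bn2");
      if (blk.down) {
        blk.dc.shape(px + ".down", 1, 1, stride, 0, cin, cout, h, w);
        blk.dc.W = conv_w_in(params[px + ".down.w"], 1, 1, cin, cout);
        blk.dbn.shape(px + ".downbn", cout, blk.dc.hout * blk.dc.wout);
        bn_in(blk.dbn, params, px + ".downbn");
      }
      h = blk.c1.hout; w = blk.c1.wout; cin = cout;
      net.blocks.push_back(std::move(blk));
    }
  }
  net.hlast = h; net.wlast = w; net.clast = cin;
  NumericMatrix fw = params["fc.w"];
  if (fw.nrow() != net.ncls || fw.ncol() != net.clast)
    stop("fc.w has shape %dx%d, expected %dx%d", fw.nrow(), fw.ncol(),
         net.ncls, net.clast);
  net.fcW.set_size(net.ncls, net.clast);
  for (int i = 0; i < net.ncls; ++i)
    for (int j = 0; j < net.clast; ++j) net.fcW(i, j) = (float)fw(i, j);
  net.fcb = vec_in(params["fc.b"]);
  return net;
}

static void bn_out(const BN& L, List& params, const std::string& prefix) {
  params[prefix + ".gamma"] = vec_out(L.gamma);
  params[prefix + ".beta"]  = vec_out(L.beta);
  params[prefix + ".rm"]    = vec_out(L.rm);
  params[prefix + ".rv"]    = vec_out(L.rv);
}

static List net_params(const Net& net) {
  List p;
  p["conv1.w"] = conv_w_out(net.conv1.W, 7, 7, 3, net.W0);
  bn_out(net.bn1, p, "bn1");
  for (const Block& b : net.blocks) {
    const std::string px = b.c1.name.substr(0, b.c1.name.size() - 6);
    p[px + ".conv1.w"] = conv_w_out(b.c1.W, 3, 3, b.c1.cin, b.c1.cout);
    bn_out(b.b1, p, px + ".bn1");
    p[px + ".conv2.w"] = conv_w_out(b.c2.W, 3, 3, b.c2.cin, b.c2.cout);
    bn_out(b.b2, p, px + ".bn2");
    if (b.down) {
      p[px + ".down.w"] = conv_w_out(b.dc.W, 1, 1, b.dc.cin, b.dc.cout);
      bn_out(b.dbn, p, px + ".downbn");
    }
  }
  NumericMatrix fw(net.ncls, net.clast);
  for (int i = 0; i < net.ncls; ++i)
    for (int j = 0; j < net.clast; ++j) fw(i, j) = net.fcW(i, j);
  p["fc.w"] = fw;
  p["fc.b"] = vec_out(net.fcb);
  return p;
}

// ------------------------------------------------------ forward/backward

static fmat forward(Net& net, const fmat& X, bool train) {
  net.xbatch = &X;
  conv_forward(net.conv1, X, net.a1);
  bn_forward(net.bn1, net.a1, train);
  relu_(net.a1);
  fmat cur;
  pool_forward(net, net.a1, cur);
  for (Block& b : net.blocks) {
    b.in = cur;
    conv_forward(b.c1, b.in, b.a1);
    bn_forward(b.b1, b.a1, train);
    relu_(b.a1);
    fmat z2;
    conv_forward(b.c2, b.a1, z2);
    bn_forward(b.b2, z2, train);
    if (b.down) {
      fmat idn;
      conv_forward(b.dc, b.in, idn);
      bn_forward(b.dbn, idn, train);
      z2 += idn;
    } else {
      z2 += b.in;
    }
    relu_(z2);
    b.out = std::move(z2);
    cur = b.out;
  }
  const int N = X.n_cols, HW = net.hlast * net.wlast;
  net.feat.set_size(net.clast, N);
  for (int n = 0; n < N; ++n) {
    const float* a = net.blocks.back().out.colptr(n);
    for (int c = 0; c < net.clast; ++c) {
      float s = 0;
      for (int p = 0; p < HW; ++p) s += a[p + HW * c];
      net.feat(c, n) = s / HW;
    }
  }
  fmat logits = net.fcW * net.feat;
  logits.each_col() += net.fcb;
  return logits;
}

// Backward from dlogits. If stop_stage >= 1, stops after computing the
// gradient w.r.t. the (post-ReLU) output of the last block of that stage
// and returns it; otherwise runs to the stem and returns an empty matrix.
static fmat backward(Net& net, const fmat& dlogits, bool train,
                     int stop_stage = -1) {
  const int N = dlogits.n_cols, HW = net.hlast * net.wlast;
  if (train) {
    net.fcdW += dlogits * net.feat.t();
    net.fcdb += arma::sum(dlogits, 1);
  }
  fmat dfeat = net.fcW.t() * dlogits;       // (clast, N)
  fmat dout(HW * net.clast, N);
  for (int n = 0; n < N; ++n) {
    float* d = dout.colptr(n);
    for (int c = 0; c < net.clast; ++c) {
      const float v = dfeat(c, n) / HW;
      for (int p = 0; p < HW; ++p) d[p + HW * c] = v;
    }
  }
  for (int bi = (int)net.blocks.size() - 1; bi >= 0; --bi) {
    Block& b = net.blocks[bi];
    const bool last_of_stage =
      (bi + 1 == (int)net.blocks.size()) || (net.blocks[bi + 1].stage != b.stage);
    if (stop_stage >= 1 && b.stage == stop_stage && last_of_stage)
      return dout;
    relu_mask_(dout, b.out);                 // gradient at z2 + skip
    fmat g = dout;                           // skip-branch share
    bn_backward(b.b2, dout, train);
    fmat da1(b.a1.n_rows, N, arma::fill::zeros);
    conv_backward(b.c2, b.a1, dout, &da1);
    relu_mask_(da1, b.a1);
    bn_backward(b.b1, da1, train);
    fmat din(b.in.n_rows, N, arma::fill::zeros);
    conv_backward(b.c1, b.in, da1, &din);
    if (b.down) {
      bn_backward(b.dbn, g, train);
      conv_backward(b.dc, b.in, g, &din);
    } else {
      din += g;
    }
    dout = std::move(din);
  }
  fmat da1;
  pool_backward(net, dout, da1);
  relu_mask_(da1, net.a1);
  bn_backward(net.bn1, da1, train);
  conv_backward(net.conv1, *net.xbatch, da1, nullptr);
  return fmat();
}

// ----------------------------------------------------------- optimizer

static void grad_zero(Net& net) {
  auto z = [](Conv& c) { c.dW.zeros(c.W.n_rows, c.W.n_cols);
                         if (c.vW.n_elem == 0) c.vW.zeros(c.W.n_rows, c.W.n_cols); };
  auto zb = [](BN& b) {
    b.dgamma.zeros(b.C); b.dbeta.zeros(b.C);
    if (b.vgamma.n_elem == 0) { b.vgamma.zeros(b.C); b.vbeta.zeros(b.C); }
  };
  z(net.conv1); zb(net.bn1);
  for (Block& b : net.blocks) {
    z(b.c1); zb(b.b1); z(b.c2); zb(b.b2);
    if (b.down) { z(b.dc); zb(b.dbn); }
  }
  net.fcdW.zeros(net.fcW.n_rows, net.fcW.n_cols);
  net.fcdb.zeros(net.fcb.n_elem);
  if (net.fcvW.n_elem == 0) { net.fcvW.zeros(net.fcW.n_rows, net.fcW.n_cols);
                              net.fcvb.zeros(net.fcb.n_elem); }
}

static void sgd_step(Net& net, float lr, float mom) {
  auto up = [&](Conv& c) {
    if (c.frozen) return;
    c.vW = mom * c.vW + c.dW;
    c.W -= lr * c.vW;
  };
  auto upb = [&](BN& b) {
    if (b.frozen) return;
    b.vgamma = mom * b.vgamma + b.dgamma; b.gamma -= lr * b.vgamma;
    b.vbeta  = mom * b.vbeta  + b.dbeta;  b.beta  -= lr * b.vbeta;
  };
  up(net.conv1); upb(net.bn1);
  for (Block& b : net.blocks) {
    up(b.c1); upb(b.b1); up(b.c2); upb(b.b2);
    if (b.down) { up(b.dc); upb(b.dbn); }
  }
  if (!net.fc_frozen) {
    net.fcvW = mom * net.fcvW + net.fcdW; net.fcW -= lr * net.fcvW;
    net.fcvb = mom * net.fcvb + net.fcdb; net.fcb -= lr * net.fcvb;
  }
}

static void set_frozen(Net& net, int freeze_up_to_stage) {
  if (freeze_up_to_stage < 0) return;
  net.conv1.frozen = net.bn1.frozen = true;
  for (Block& b : net.blocks)
    if (b.stage <= freeze_up_to_stage) {
      b.c1.frozen = b.b1.frozen = b.c2.frozen = b.b2.frozen = true;
      if (b.down) { b.dc.frozen = b.dbn.frozen = true; }
    }
}

// --------------------------------------------------------------- helpers

static fmat to_fmat(const NumericMatrix& X) {
  fmat out(X.nrow(), X.ncol());
  const double* src = X.begin();
  float* dst = out.memptr();
  const R_xlen_t n = (R_xlen_t)X.nrow() * X.ncol();
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = (float)src[i];
  return out;
}

static fmat softmax_cols(const fmat& logits) {
  fmat p = logits;
  for (arma::uword n = 0; n < p.n_cols; ++n) {
    fvec c = p.col(n);
    c -= c.max();
    c = arma::exp(c);
    p.col(n) = c / arma::accu(c);
  }
  return p;
}

static double eval_accuracy(Net& net, const fmat& X, const arma::ivec& y,
                            int batch) {
  int correct = 0;
  for (arma::uword s = 0; s < X.n_cols; s += batch) {
    const arma::uword e = std::min<arma::uword>(s + batch, X.n_cols) - 1;
    fmat logits = forward(net, X.cols(s, e), false);
    for (arma::uword n = 0; n < logits.n_cols; ++n)
      if ((logits(1, n) > logits(0, n) ? 1 : 0) == y[s + n]) ++correct;
  }
  return (double)correct / X.n_cols;
}

// ------------------------------------------------------------- exports

// [[Rcpp::export]]
List cpp_train(List params, List config, NumericMatrix X, IntegerVector y,
               NumericMatrix Xval, IntegerVector yval, double lr,
               double momentum, int epochs, int batch, int seed,
               int freeze_up_to_stage) {
  Net net = build_net(params, config);
  set_frozen(net, freeze_up_to_stage);
  fmat Xt = to_fmat(X), Xv = to_fmat(Xval);
  arma::ivec yt(y.size()), yv(yval.size());
  for (R_xlen_t i = 0; i < y.size(); ++i) yt[i] = y[i];
  for (R_xlen_t i = 0; i < yval.size(); ++i) yv[i] = yval[i];
  const int ntr = Xt.n_cols;
  if (ntr == 0) stop("empty training set");

  std::mt19937 rng((unsigned)seed);
  std::vector<int> perm(ntr);
  for (int i = 0; i < ntr; ++i) perm[i] = i;

  NumericVector ep(epochs), tr_loss(epochs), tr_acc(epochs), va_acc(epochs);
  LogicalVector is_best(epochs);
  double best_acc = -1.0;
  int best_epoch = -1;
  List best_params;

  for (int e = 0; e < epochs; ++e) {
    // Fisher-Yates with explicit draws so shuffling is reproducible
    // independent of the C++ standard library implementation
    for (int i = ntr - 1; i > 0; --i) {
      const int j = (int)(rng() % (unsigned)(i + 1));
      std::swap(perm[i], perm[j]);
    }
    double loss_sum = 0; int correct = 0;
    for (int s = 0; s < ntr; s += batch) {
      const int nb = std::min(batch, ntr - s);
      fmat Xb(Xt.n_rows, nb);
      arma::ivec yb(nb);
      for (int k = 0; k < nb; ++k) {
        Xb.col(k) = Xt.col(perm[s + k]);
        yb[k] = yt[perm[s + k]];
      }
      grad_zero(net);
      fmat logits = forward(net, Xb, true);
      fmat probs = softmax_cols(logits);
      fmat dlogits = probs;
      for (int k = 0; k < nb; ++k) {
        const float p = std::max(probs(yb[k], k), 1e-12f);
        loss_sum += -std::log(p);
        if ((probs(1, k) > probs(0, k) ? 1 : 0) == yb[k]) ++correct;
        dlogits(yb[k], k) -= 1.0f;
      }
      if (!std::isfinite(loss_sum))
        stop("training diverged (non-finite loss) at epoch %d", e + 1);
      dlogits /= (float)nb;
      backward(net, dlogits, true);
      sgd_step(net, (float)lr, (float)momentum);
    }
    ep[e] = e + 1;
    tr_loss[e] = loss_sum / ntr;
    tr_acc[e] = (double)correct / ntr;
    va_acc[e] = (Xv.n_cols > 0) ? eval_accuracy(net, Xv, yv, batch)
                                : tr_acc[e];
    if (va_acc[e] > best_acc) {
      best_acc = va_acc[e];
      best_epoch = e + 1;
      best_params = net_params(net);
      is_best[e] = true;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["epoch"] = ep, _["train_loss"] = tr_loss, _["train_accuracy"] = tr_acc,
    _["val_accuracy"] = va_acc, _["is_best_so_far"] = is_best,
    _["best_epoch"] = best_epoch, _["best_val_accuracy"] = best_acc,
    _["best_params"] = best_params, _["final_params"] = net_params(net));
}

// [[Rcpp::export]]
NumericMatrix cpp_predict(List params, List config, NumericMatrix X,
                          int batch = 32) {
  Net net = build_net(params, config);
  fmat Xf = to_fmat(X);
  NumericMatrix out(Xf.n_cols, 2);
  for (arma::uword s = 0; s < Xf.n_cols; s += batch) {
    const arma::uword e = std::min<arma::uword>(s + batch, Xf.n_cols) - 1;
    fmat probs = softmax_cols(forward(net, Xf.cols(s, e), false));
    for (arma::uword n = 0; n < probs.n_cols; ++n) {
      out(s + n, 0) = probs(0, n);
      out(s + n, 1) = probs(1, n);
    }
  }
  return out;
}

// Feature maps of a stage's output plus the gradient of one class logit
// with respect to them (eval-mode BN), for Grad-CAM.
// [[Rcpp::export]]
List cpp_stage_grad(List params, List config, NumericVector x, int class_idx,
                    int stage) {
  Net net = build_net(params, config);
  if (stage < 1 || stage > net.S) stop("stage must lie in 1..%d", net.S);
  if (class_idx < 0 || class_idx >= net.ncls) stop("bad class index");
  fmat X(net.d_in, 1);
  for (int i = 0; i < net.d_in; ++i) X(i, 0) = (float)x[i];
  fmat logits = forward(net, X, false);

  // locate the stage's terminal block and copy its output
  int bidx = -1;
  for (int i = 0; i < (int)net.blocks.size(); ++i)
    if (net.blocks[i].stage == stage) bidx = i;
  const Block& tb = net.blocks[bidx];
  const int h = tb.c1.hout, w = tb.c1.wout, C = tb.c1.cout;

  fmat dlogits(net.ncls, 1, arma::fill::zeros);
  dlogits(class_idx, 0) = 1.0f;
  fmat dA = backward(net, dlogits, false, stage);

  NumericVector feats(h * (R_xlen_t)w * C), grads(h * (R_xlen_t)w * C);
  const float* f = tb.out.colptr(0);
  const float* g = dA.colptr(0);
  for (R_xlen_t i = 0; i < feats.size(); ++i) { feats[i] = f[i]; grads[i] = g[i]; }
  feats.attr("dim") = IntegerVector::create(h, w, C);
  grads.attr("dim") = IntegerVector::create(h, w, C);
  return List::create(_["features"] = feats, _["grad"] = grads,
                      _["logits"] = NumericVector::create(logits(0, 0),
                                                          logits(1, 0)));
}

// Eval-mode stage activations (used in tests against an R-level oracle).
// [[Rcpp::export]]
List cpp_stage_features(List params, List config, NumericVector x, int stage) {
  Net net = build_net(params, config);
  if (stage < 1 || stage > net.S) stop("stage must lie in 1..%d", net.S);
  fmat X(net.d_in, 1);
  for (int i = 0; i < net.d_in; ++i) X(i, 0) = (float)x[i];
  fmat logits = forward(net, X, false);
  int bidx = -1;
  for (int i = 0; i < (int)net.blocks.size(); ++i)
    if (net.blocks[i].stage == stage) bidx = i;
  const Block& tb = net.blocks[bidx];
  const int h = tb.c1.hout, w = tb.c1.wout, C = tb.c1.cout;
  NumericVector feats(h * (R_xlen_t)w * C);
  const float* f = tb.out.colptr(0);
  for (R_xlen_t i = 0; i < feats.size(); ++i) feats[i] = f[i];
  feats.attr("dim") = IntegerVector::create(h, w, C);
  return List::create(_["features"] = feats,
                      _["logits"] = NumericVector::create(logits(0, 0),
                                                          logits(1, 0)));
}
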