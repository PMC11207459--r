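// Whole-network forward/backward for the small 3-level U-Net, kept in
// single precision end to end to avoid per-layer R round trips.
// Activation storage: fmat (H*W) x (C*N); column c + C*n is the HxW
// plane of channel c, sample n (so each sample block is contiguous and
// im2col can run on it directly).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::umat;

// from nn_ops.cpp
void im2col_f(const float* x, int H, int W, int C,
              int kh, int kw, int sh, int sw, int ph, int pw, fmat& K);
void col2im_add_f(const fmat& K, int H, int W, int C,
                  int kh, int kw, int sh, int sw, int ph, int pw, float* dx);

namespace {

struct ConvP {
  fmat W;   // (kh*kw*Cin) x Cout
  fvec b;
  int kh, kw, cin, cout;
};

ConvP get_conv(const List& params, const char* name) {
  List p = params[name];
  NumericVector w = p["W"], b = p["b"];
  IntegerVector wd = w.attr("dim");
  ConvP out;
  out.kh = wd[0]; out.kw = wd[1]; out.cin = wd[2]; out.cout = wd[3];
  out.W.set_size(out.kh * out.kw * out.cin, out.cout);
  for (size_t i = 0; i < out.W.n_elem; ++i) out.W[i] = (float)w[i];
  out.b.set_size(out.cout);
  for (int i = 0; i < out.cout; ++i) out.b[i] = (float)b[i];
  return out;
}

fmat conv_fwd(const fmat& X, int H, int W, int N, const ConvP& cp,
              int ph, int pw, int& Ho, int& Wo) {
  Ho = H + 2 * ph - cp.kh + 1;
  Wo = W + 2 * pw - cp.kw + 1;
  fmat Y((size_t)Ho * Wo, (size_t)cp.cout * N);
  fmat K((size_t)Ho * Wo, (size_t)cp.kh * cp.kw * cp.cin);
  for (int n = 0; n < N; ++n) {
    im2col_f(X.memptr() + (size_t)H * W * cp.cin * n, H, W, cp.cin,
             cp.kh, cp.kw, 1, 1, ph, pw, K);
    fmat Yn = K * cp.W;
    Yn.each_row() += cp.b.t();
    Y.cols((size_t)cp.cout * n, (size_t)cp.cout * (n + 1) - 1) = Yn;
  }
  return Y;
}

// dY -> dX; accumulates dW/db into gW/gb
fmat conv_bwd(const fmat& X, int H, int W, int N, const ConvP& cp,
              int ph, int pw, const fmat& dY, int Ho, int Wo,
              fmat& gW, fvec& gb) {
  fmat dX(arma::size(X), arma::fill::zeros);
  fmat K((size_t)Ho * Wo, (size_t)cp.kh * cp.kw * cp.cin);
  for (int n = 0; n < N; ++n) {
    im2col_f(X.memptr() + (size_t)H * W * cp.cin * n, H, W, cp.cin,
             cp.kh, cp.kw, 1, 1, ph, pw, K);
    fmat dYn = dY.cols((size_t)cp.cout * n, (size_t)cp.cout * (n + 1) - 1);
    gW += K.t() * dYn;
    gb += arma::sum(dYn, 0).t();
    fmat dK = dYn * cp.W.t();
    col2im_add_f(dK, H, W, cp.cin, cp.kh, cp.kw, 1, 1, ph, pw,
                 const_cast<float*>(dX.memptr()) + (size_t)H * W * cp.cin * n);
  }
  return dX;
}

void relu_fwd(fmat& A) { A.clamp(0.0f, std::numeric_limits<float>::max()); }
void relu_bwd(const fmat& Y, fmat& dY) {
  for (size_t i = 0; i < Y.n_elem; ++i) if (Y[i] <= 0.0f) dY[i] = 0.0f;
}

fmat pool_fwd(const fmat& X, int H, int W, umat& idx) {
  const int Ho = H / 2, Wo = W / 2;
  fmat Y((size_t)Ho * Wo, X.n_cols);
  idx.set_size((size_t)Ho * Wo, X.n_cols);
  for (size_t c = 0; c < X.n_cols; ++c) {
    const float* pl = X.colptr(c);
    float* yp = Y.colptr(c);
    arma::uword* ip = idx.colptr(c);
    size_t o = 0;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho, ++o) {
        int best = 2 * ho + H * 2 * wo;
        float bv = pl[best];
        const int cand[3] = {2 * ho + 1 + H * 2 * wo, 2 * ho + H * (2 * wo + 1),
                             2 * ho + 1 + H * (2 * wo + 1)};
        for (int k = 0; k < 3; ++k)
          if (pl[cand[k]] > bv) { bv = pl[cand[k]]; best = cand[k]; }
        yp[o] = bv; ip[o] = best;
      }
  }
  return Y;
}

fmat pool_bwd(const fmat& dY, const umat& idx, int H, int W) {
  fmat dX((size_t)H * W, dY.n_cols, arma::fill::zeros);
  for (size_t c = 0; c < dY.n_cols; ++c) {
    float* dp = dX.colptr(c);
    const float* yp = dY.colptr(c);
    const arma::uword* ip = idx.colptr(c);
    for (size_t i = 0; i < dY.n_rows; ++i) dp[ip[i]] += yp[i];
  }
  return dX;
}

fmat up_fwd(const fmat& X, int H, int W) {
  const int Ho = 2 * H, Wo = 2 * W;
  fmat Y((size_t)Ho * Wo, X.n_cols);
  for (size_t c = 0; c < X.n_cols; ++c) {
    const float* xp = X.colptr(c);
    float* yp = Y.colptr(c);
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const float v = xp[h + H * w];
        float* o = yp + 2 * h + Ho * 2 * w;
        o[0] = v; o[1] = v; o[Ho] = v; o[Ho + 1] = v;
      }
  }
  return Y;
}

fmat up_bwd(const fmat& dY, int H, int W) {
  const int Ho = 2 * H;
  fmat dX((size_t)H * W, dY.n_cols);
  for (size_t c = 0; c < dY.n_cols; ++c) {
    const float* yp = dY.colptr(c);
    float* xp = dX.colptr(c);
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const float* o = yp + 2 * h + Ho * 2 * w;
        xp[h + H * w] = o[0] + o[1] + o[Ho] + o[Ho + 1];
      }
  }
  return dX;
}

fmat cat_ch(const fmat& A, int Ca, const fmat& B, int Cb, int N) {
  fmat out(A.n_rows, (size_t)(Ca + Cb) * N);
  for (int n = 0; n < N; ++n) {
    out.cols((size_t)(Ca + Cb) * n, (size_t)(Ca + Cb) * n + Ca - 1) =
      A.cols((size_t)Ca * n, (size_t)Ca * (n + 1) - 1);
    out.cols((size_t)(Ca + Cb) * n + Ca, (size_t)(Ca + Cb) * (n + 1) - 1) =
      B.cols((size_t)Cb * n, (size_t)Cb * (n + 1) - 1);
  }
  return out;
}

void split_ch(const fmat& D, int Ca, int Cb, int N, fmat& dA, fmat& dB) {
  dA.set_size(D.n_rows, (size_t)Ca * N);
  dB.set_size(D.n_rows, (size_t)Cb * N);
  for (int n = 0; n < N; ++n) {
    dA.cols((size_t)Ca * n, (size_t)Ca * (n + 1) - 1) =
      D.cols((size_t)(Ca + Cb) * n, (size_t)(Ca + Cb) * n + Ca - 1);
    dB.cols((size_t)Cb * n, (size_t)Cb * (n + 1) - 1) =
      D.cols((size_t)(Ca + Cb) * n + Ca, (size_t)(Ca + Cb) * (n + 1) - 1);
  }
}

struct UNetActs {
  fmat x, e1, e1b, p1, e2, e2b, p2, b1, b2, u2, c2, d2, u1, c1, d1, prob;
  umat i1, i2;
};

struct UNetParams {
  ConvP e1c1, e1c2, e2c1, e2c2, bc1, bc2, d2, d1, out;
};

UNetParams load_params(const List& params) {
  UNetParams P;
  P.e1c1 = get_conv(params, "e1c1"); P.e1c2 = get_conv(params, "e1c2");
  P.e2c1 = get_conv(params, "e2c1"); P.e2c2 = get_conv(params, "e2c2");
  P.bc1 = get_conv(params, "bc1");   P.bc2 = get_conv(params, "bc2");
  P.d2 = get_conv(params, "d2");     P.d1 = get_conv(params, "d1");
  P.out = get_conv(params, "out");
  return P;
}

void forward(const UNetParams& P, const fmat& x, int H, int W, int N,
             UNetActs& A) {
  int ho, wo;
  A.x = x;
  A.e1 = conv_fwd(A.x, H, W, N, P.e1c1, 1, 1, ho, wo); relu_fwd(A.e1);
  A.e1b = conv_fwd(A.e1, H, W, N, P.e1c2, 1, 1, ho, wo); relu_fwd(A.e1b);
  A.p1 = pool_fwd(A.e1b, H, W, A.i1);
  const int H2 = H / 2, W2 = W / 2;
  A.e2 = conv_fwd(A.p1, H2, W2, N, P.e2c1, 1, 1, ho, wo); relu_fwd(A.e2);
  A.e2b = conv_fwd(A.e2, H2, W2, N, P.e2c2, 1, 1, ho, wo); relu_fwd(A.e2b);
  A.p2 = pool_fwd(A.e2b, H2, W2, A.i2);
  const int H4 = H2 / 2, W4 = W2 / 2;
  A.b1 = conv_fwd(A.p2, H4, W4, N, P.bc1, 1, 1, ho, wo); relu_fwd(A.b1);
  A.b2 = conv_fwd(A.b1, H4, W4, N, P.bc2, 1, 1, ho, wo); relu_fwd(A.b2);
  A.u2 = up_fwd(A.b2, H4, W4);
  A.c2 = cat_ch(A.u2, P.bc2.cout, A.e2b, P.e2c2.cout, N);
  A.d2 = conv_fwd(A.c2, H2, W2, N, P.d2, 1, 1, ho, wo); relu_fwd(A.d2);
  A.u1 = up_fwd(A.d2, H2, W2);
  A.c1 = cat_ch(A.u1, P.d2.cout, A.e1b, P.e1c2.cout, N);
  A.d1 = conv_fwd(A.c1, H, W, N, P.d1, 1, 1, ho, wo); relu_fwd(A.d1);
  fmat logit = conv_fwd(A.d1, H, W, N, P.out, 0, 0, ho, wo);
  A.prob = 1.0f / (1.0f + arma::exp(-logit));
}

} // namespace

// [[Rcpp::export]]
List cpp_unet_train_step(NumericVector x, NumericVector g, List params,
                         double smooth) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], N = xd[3];
  fmat xf((size_t)H * W, (size_t)N), gf((size_t)H * W, (size_t)N);
  for (size_t i = 0; i < xf.n_elem; ++i) { xf[i] = (float)x[i]; gf[i] = (float)g[i]; }
  UNetParams P = load_params(params);
  UNetActs A;
  forward(P, xf, H, W, N, A);

  // soft Dice loss and gradient
  const double num = 2.0 * arma::dot(A.prob, gf) + smooth;
  const double den = arma::accu(A.prob) + arma::accu(gf) + smooth;
  const double loss = 1.0 - num / den;
  fmat dprob = -(2.0f * gf * (float)den - (float)num) / (float)(den * den);
  fmat dlogit = dprob % A.prob % (1.0f - A.prob);

  const int H2 = H / 2, W2 = W / 2, H4 = H / 4, W4 = W / 4;
  UNetParams G = P;   // same shapes; zero them
  fmat* gws[] = {&G.e1c1.W, &G.e1c2.W, &G.e2c1.W, &G.e2c2.W, &G.bc1.W,
                 &G.bc2.W, &G.d2.W, &G.d1.W, &G.out.W};
  fvec* gbs[] = {&G.e1c1.b, &G.e1c2.b, &G.e2c1.b, &G.e2c2.b, &G.bc1.b,
                 &G.bc2.b, &G.d2.b, &G.d1.b, &G.out.b};
  for (int i = 0; i < 9; ++i) { gws[i]->zeros(); gbs[i]->zeros(); }

  fmat dd1 = conv_bwd(A.d1, H, W, N, P.out, 0, 0, dlogit, H, W,
                      G.out.W, G.out.b);
  relu_bwd(A.d1, dd1);
  fmat dc1 = conv_bwd(A.c1, H, W, N, P.d1, 1, 1, dd1, H, W, G.d1.W, G.d1.b);
  fmat du1, de1b_skip;
  split_ch(dc1, P.d2.cout, P.e1c2.cout, N, du1, de1b_skip);
  fmat dd2 = up_bwd(du1, H2, W2);
  relu_bwd(A.d2, dd2);
  fmat dc2 = conv_bwd(A.c2, H2, W2, N, P.d2, 1, 1, dd2, H2, W2,
                      G.d2.W, G.d2.b);
  fmat du2, de2b_skip;
  split_ch(dc2, P.bc2.cout, P.e2c2.cout, N, du2, de2b_skip);
  fmat db2 = up_bwd(du2, H4, W4);
  relu_bwd(A.b2, db2);
  fmat db1 = conv_bwd(A.b1, H4, W4, N, P.bc2, 1, 1, db2, H4, W4,
                      G.bc2.W, G.bc2.b);
  relu_bwd(A.b1, db1);
  fmat dp2 = conv_bwd(A.p2, H4, W4, N, P.bc1, 1, 1, db1, H4, W4,
                      G.bc1.W, G.bc1.b);
  fmat de2b = pool_bwd(dp2, A.i2, H2, W2) + de2b_skip;
  relu_bwd(A.e2b, de2b);
  fmat de2 = conv_bwd(A.e2, H2, W2, N, P.e2c2, 1, 1, de2b, H2, W2,
                      G.e2c2.W, G.e2c2.b);
  relu_bwd(A.e2, de2);
  fmat dp1 = conv_bwd(A.p1, H2, W2, N, P.e2c1, 1, 1, de2, H2, W2,
                      G.e2c1.W, G.e2c1.b);
  fmat de1b = pool_bwd(dp1, A.i1, H, W) + de1b_skip;
  relu_bwd(A.e1b, de1b);
  fmat de1 = conv_bwd(A.e1, H, W, N, P.e1c2, 1, 1, de1b, H, W,
                      G.e1c2.W, G.e1c2.b);
  relu_bwd(A.e1, de1);
  conv_bwd(A.x, H, W, N, P.e1c1, 1, 1, de1, H, W, G.e1c1.W, G.e1c1.b);

  const char* nms[] = {"e1c1", "e1c2", "e2c1", "e2c2", "bc1", "bc2",
                       "d2", "d1", "out"};
  List grads;
  List pl(params);
  for (int i = 0; i < 9; ++i) {
    List src = pl[nms[i]];
    NumericVector wref = src["W"];
    NumericVector dw(wref.size());
    dw.attr("dim") = wref.attr("dim");
    const fmat& gm = *gws[i];
    for (size_t j = 0; j < gm.n_elem; ++j) dw[j] = gm[j];
    NumericVector db_(gbs[i]->n_elem);
    for (size_t j = 0; j < gbs[i]->n_elem; ++j) db_[j] = (*gbs[i])[j];
    grads[nms[i]] = List::create(_["dW"] = dw, _["db"] = db_);
  }
  return List::create(_["loss"] = loss, _["grads"] = grads);
}

// [[Rcpp::export]]
NumericVector cpp_unet_infer(NumericVector x, List params) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], N = xd[3];
  fmat xf((size_t)H * W, (size_t)N);
  for (size_t i = 0; i < xf.n_elem; ++i) xf[i] = (float)x[i];
  UNetParams P = load_params(params);
  UNetActs A;
  forward(P, xf, H, W, N, A);
  NumericVector out((R_xlen_t)H * W * N);
  out.attr("dim") = IntegerVector::create(H, W, 1, N);
  for (size_t i = 0; i < A.prob.n_elem; ++i) out[i] = A.prob[i];
  return out;
}
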