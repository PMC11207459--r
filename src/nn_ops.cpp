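// Minimal single-precision conv-net kernels (im2col + BLAS gemm).
// Layout conventions (column-major, as R arrays):
//   activations: dim (H, W, C, N)
//   conv weights: dim (kh, kw, Cin, Cout)
// im2col row = output pixel (ho + Ho*wo), col = kernel element
// (ky + kh*kx + kh*kw*c), so Y = K * Wmat with Wmat = reshape(w, kh*kw*Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int H, int k, int stride, int pad) {
  return (H + 2 * pad - k) / stride + 1;
}

void im2col_f(const float* x, int H, int W, int C,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   arma::fmat& K) {
  const int Ho = out_dim(H, kh, sh, ph);
  const int Wo = out_dim(W, kw, sw, pw);
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        const int col = ky + kh * (kx + kw * c);
        float* Kcol = K.colptr(col);
        const float* xc = x + (size_t)H * W * c;
        // valid output-row range for this kernel offset
        int h0 = 0; while (h0 < Ho && h0 * sh + ky - ph < 0) ++h0;
        int h1 = Ho; while (h1 > h0 && (h1 - 1) * sh + ky - ph >= H) --h1;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * sw + kx - pw;
          float* dst = Kcol + (size_t)Ho * wo;
          if (wi < 0 || wi >= W) {
            std::fill(dst, dst + Ho, 0.0f);
            continue;
          }
          const float* src = xc + (size_t)H * wi + (ky - ph);
          std::fill(dst, dst + h0, 0.0f);
          std::fill(dst + h1, dst + Ho, 0.0f);
          if (sh == 1) {
            std::copy(src + h0, src + h1, dst + h0);
          } else {
            for (int ho = h0; ho < h1; ++ho) dst[ho] = src[(size_t)ho * sh];
          }
        }
      }
    }
  }
}

void col2im_add_f(const arma::fmat& K, int H, int W, int C,
                       int kh, int kw, int sh, int sw, int ph, int pw,
                       float* dx) {
  const int Ho = out_dim(H, kh, sh, ph);
  const int Wo = out_dim(W, kw, sw, pw);
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        const int col = ky + kh * (kx + kw * c);
        const float* Kcol = K.colptr(col);
        float* xc = dx + (size_t)H * W * c;
        int h0 = 0; while (h0 < Ho && h0 * sh + ky - ph < 0) ++h0;
        int h1 = Ho; while (h1 > h0 && (h1 - 1) * sh + ky - ph >= H) --h1;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * sw + kx - pw;
          if (wi < 0 || wi >= W) continue;
          const float* src = Kcol + (size_t)Ho * wo;
          float* dst = xc + (size_t)H * wi + (ky - ph);
          if (sh == 1) {
            for (int ho = h0; ho < h1; ++ho) dst[ho] += src[ho];
          } else {
            for (int ho = h0; ho < h1; ++ho) dst[(size_t)ho * sh] += src[ho];
          }
        }
      }
    }
  }
}

static arma::fvec as_fvec(const NumericVector& v) {
  arma::fvec out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             IntegerVector stride, IntegerVector pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int sh = stride[0], sw = stride[1], ph = pad[0], pw = pad[1];
  if (Cin != C) stop("channel mismatch");
  const int Ho = out_dim(H, kh, sh, ph), Wo = out_dim(W, kw, sw, pw);
  arma::fvec xf = as_fvec(x);
  arma::fmat Wmat(as_fvec(w).memptr(), kh * kw * Cin, Cout, true);
  arma::fvec bf = as_fvec(b);
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::fmat K((size_t)Ho * Wo, (size_t)kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    im2col_f(xf.memptr() + (size_t)H * W * C * n, H, W, C, kh, kw,
           sh, sw, ph, pw, K);
    arma::fmat Y = K * Wmat;            // (Ho*Wo) x Cout
    Y.each_row() += bf.t();
    double* yp = REAL(y) + (size_t)Ho * Wo * Cout * n;
    const float* src = Y.memptr();
    for (size_t i = 0; i < (size_t)Ho * Wo * Cout; ++i) yp[i] = src[i];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    IntegerVector stride, IntegerVector pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int sh = stride[0], sw = stride[1], ph = pad[0], pw = pad[1];
  const int Ho = yd[0], Wo = yd[1];
  arma::fvec xf = as_fvec(x), dyf = as_fvec(dy);
  arma::fmat Wmat(as_fvec(w).memptr(), kh * kw * Cin, Cout, true);
  arma::fmat dW(kh * kw * Cin, Cout, arma::fill::zeros);
  arma::fvec db(Cout, arma::fill::zeros);
  arma::fvec dxf((size_t)H * W * C * N, arma::fill::zeros);
  arma::fmat K((size_t)Ho * Wo, (size_t)kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    arma::fmat dY(dyf.memptr() + (size_t)Ho * Wo * Cout * n,
                  (size_t)Ho * Wo, Cout, false, true);
    im2col_f(xf.memptr() + (size_t)H * W * C * n, H, W, C, kh, kw,
           sh, sw, ph, pw, K);
    dW += K.t() * dY;
    db += arma::sum(dY, 0).t();
    arma::fmat dK = dY * Wmat.t();      // (Ho*Wo) x (kh*kw*Cin)
    col2im_add_f(dK, H, W, C, kh, kw, sh, sw, ph, pw,
               dxf.memptr() + (size_t)H * W * C * n);
  }
  NumericVector dx((R_xlen_t)dxf.n_elem), dwv((R_xlen_t)dW.n_elem), dbv(Cout);
  dx.attr("dim") = xd;
  dwv.attr("dim") = wd;
  for (size_t i = 0; i < dxf.n_elem; ++i) REAL(dx)[i] = dxf[i];
  const float* dwp = dW.memptr();
  for (size_t i = 0; i < dW.n_elem; ++i) REAL(dwv)[i] = dwp[i];
  for (int i = 0; i < Cout; ++i) REAL(dbv)[i] = db[i];
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
}
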