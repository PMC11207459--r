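// Whole-network forward/backward for the 1D area CNN, single precision.
// Layout: 1D signals run down the H axis (kernel kh x 1, stride 2x1,
// pad ph x 0); activations are fmat (L, C*N) as in unet.cpp. The head
// is flatten -> hidden dense (ReLU) -> linear output that also sees the
// raw input profile through a skip path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

void im2col_f(const float* x, int H, int W, int C,
              int kh, int kw, int sh, int sw, int ph, int pw, fmat& K);
void col2im_add_f(const fmat& K, int H, int W, int C,
                  int kh, int kw, int sh, int sw, int ph, int pw, float* dx);

namespace {

struct ConvP1 {
  fmat W;
  fvec b;
  int kh, cin, cout;
};

struct DenseP {
  fmat W;   // n_in x n_out
  fvec b;
};

ConvP1 get_conv1(const List& params, const char* name) {
  List p = params[name];
  NumericVector w = p["W"], b = p["b"];
  IntegerVector wd = w.attr("dim");
  ConvP1 out;
  out.kh = wd[0]; out.cin = wd[2]; out.cout = wd[3];
  out.W.set_size(out.kh * out.cin, out.cout);
  for (size_t i = 0; i < out.W.n_elem; ++i) out.W[i] = (float)w[i];
  out.b.set_size(out.cout);
  for (int i = 0; i < out.cout; ++i) out.b[i] = (float)b[i];
  return out;
}

DenseP get_dense(const List& params, const char* name) {
  List p = params[name];
  NumericMatrix w = p["W"];
  NumericVector b = p["b"];
  DenseP out;
  out.W.set_size(w.nrow(), w.ncol());
  for (size_t i = 0; i < out.W.n_elem; ++i) out.W[i] = (float)w[i];
  out.b.set_size(b.size());
  for (R_xlen_t i = 0; i < b.size(); ++i) out.b[i] = (float)b[i];
  return out;
}

int out_len(int L, int kh) { return (L + 2 * 4 - kh) / 2 + 1; }

fmat conv1_fwd(const fmat& X, int L, int N, const ConvP1& cp, int& Lo) {
  Lo = out_len(L, cp.kh);
  fmat Y((size_t)Lo, (size_t)cp.cout * N);
  fmat K((size_t)Lo, (size_t)cp.kh * cp.cin);
  for (int n = 0; n < N; ++n) {
    im2col_f(X.memptr() + (size_t)L * cp.cin * n, L, 1, cp.cin,
             cp.kh, 1, 2, 1, 4, 0, K);
    fmat Yn = K * cp.W;
    Yn.each_row() += cp.b.t();
    Y.cols((size_t)cp.cout * n, (size_t)cp.cout * (n + 1) - 1) = Yn;
  }
  return Y;
}

fmat conv1_bwd(const fmat& X, int L, int N, const ConvP1& cp,
               const fmat& dY, int Lo, fmat& gW, fvec& gb) {
  fmat dX(arma::size(X), arma::fill::zeros);
  fmat K((size_t)Lo, (size_t)cp.kh * cp.cin);
  for (int n = 0; n < N; ++n) {
    im2col_f(X.memptr() + (size_t)L * cp.cin * n, L, 1, cp.cin,
             cp.kh, 1, 2, 1, 4, 0, K);
    fmat dYn = dY.cols((size_t)cp.cout * n, (size_t)cp.cout * (n + 1) - 1);
    gW += K.t() * dYn;
    gb += arma::sum(dYn, 0).t();
    fmat dK = dYn * cp.W.t();
    col2im_add_f(dK, L, 1, cp.cin, cp.kh, 1, 2, 1, 4, 0,
                 const_cast<float*>(dX.memptr()) + (size_t)L * cp.cin * n);
  }
  return dX;
}

void relu_ip(fmat& A) { A.clamp(0.0f, std::numeric_limits<float>::max()); }
void relu_bw(const fmat& Y, fmat& dY) {
  for (size_t i = 0; i < Y.n_elem; ++i) if (Y[i] <= 0.0f) dY[i] = 0.0f;
}

} // namespace

// x: matrix (n_input x N) of profiles; y: vector length N (ignored when
// train = false). params: c1..c4, fc, head. Returns loss + grads, or
// predictions when train = false.
// [[Rcpp::export]]
List cpp_cnn1d_run(NumericMatrix x, NumericVector y, List params,
                   double delta, bool train) {
  const int L0 = x.nrow(), N = x.ncol();
  int n_conv = 0;
  while (params.containsElementNamed(
           (std::string("c") + std::to_string(n_conv + 1)).c_str()))
    ++n_conv;
  std::vector<ConvP1> cps(n_conv);
  for (int i = 0; i < n_conv; ++i)
    cps[i] = get_conv1(params, (std::string("c") + std::to_string(i + 1)).c_str());
  DenseP fc = get_dense(params, "fc"), head = get_dense(params, "head");

  fmat X0((size_t)L0, (size_t)N);
  for (size_t i = 0; i < X0.n_elem; ++i) X0[i] = (float)x[i];

  std::vector<fmat> acts(n_conv + 1);
  std::vector<int> lens(n_conv + 1);
  acts[0] = X0; lens[0] = L0;
  for (int i = 0; i < n_conv; ++i) {
    int Lo;
    acts[i + 1] = conv1_fwd(acts[i], lens[i], N, cps[i], Lo);
    relu_ip(acts[i + 1]);
    lens[i + 1] = Lo;
  }
  const int flat_dim = lens[n_conv] * cps[n_conv - 1].cout;
  fmat F(const_cast<float*>(acts[n_conv].memptr()), flat_dim, N, false, true);
  fmat hid = fc.W.t() * F;            // hidden x N
  hid.each_col() += fc.b;
  relu_ip(hid);
  const int nh = hid.n_rows;
  fmat hx(nh + L0, N);
  hx.rows(0, nh - 1) = hid;
  hx.rows(nh, nh + L0 - 1) = X0;
  fmat out = head.W.t() * hx;         // 1 x N
  out.each_col() += head.b;

  if (!train) {
    NumericVector pred(N);
    for (int n = 0; n < N; ++n) pred[n] = out(0, n);
    return List::create(_["pred"] = pred);
  }

  // Huber loss and gradient
  double loss = 0.0;
  fmat dout(1, N);
  for (int n = 0; n < N; ++n) {
    const double r = out(0, n) - y[n];
    const double a = std::fabs(r);
    if (a <= delta) { loss += 0.5 * r * r; dout(0, n) = (float)(r / N); }
    else { loss += delta * (a - 0.5 * delta);
           dout(0, n) = (float)(delta * ((r > 0) - (r < 0)) / (double)N); }
  }
  loss /= N;

  fmat gHeadW = hx * dout.t();
  fvec gHeadb(1); gHeadb[0] = arma::accu(dout);
  fmat dhx = head.W * dout;           // (nh + L0) x N
  fmat dhid = dhx.rows(0, nh - 1);
  relu_bw(hid, dhid);
  fmat gFcW = F * dhid.t();
  fvec gFcb = arma::sum(dhid, 1);
  fmat dF = fc.W * dhid;              // flat_dim x N
  fmat dA(dF.memptr(), (size_t)lens[n_conv],
          (size_t)cps[n_conv - 1].cout * N, false, true);

  List grads;
  fmat dcur = dA;
  std::vector<fmat> gW(n_conv);
  std::vector<fvec> gb(n_conv);
  for (int i = n_conv - 1; i >= 0; --i) {
    gW[i].zeros(cps[i].kh * cps[i].cin, cps[i].cout);
    gb[i].zeros(cps[i].cout);
    relu_bw(acts[i + 1], dcur);
    dcur = conv1_bwd(acts[i], lens[i], N, cps[i], dcur, lens[i + 1],
                     gW[i], gb[i]);
  }
  for (int i = 0; i < n_conv; ++i) {
    std::string nm = "c" + std::to_string(i + 1);
    List src = params[nm];
    NumericVector wref = src["W"];
    NumericVector dw(wref.size());
    dw.attr("dim") = wref.attr("dim");
    for (size_t j = 0; j < gW[i].n_elem; ++j) dw[j] = gW[i][j];
    NumericVector db(gb[i].n_elem);
    for (size_t j = 0; j < gb[i].n_elem; ++j) db[j] = gb[i][j];
    grads[nm] = List::create(_["dW"] = dw, _["db"] = db);
  }
  NumericMatrix gfw(fc.W.n_rows, fc.W.n_cols);
  for (size_t j = 0; j < gFcW.n_elem; ++j) gfw[j] = gFcW[j];
  NumericVector gfb(gFcb.n_elem);
  for (size_t j = 0; j < gFcb.n_elem; ++j) gfb[j] = gFcb[j];
  grads["fc"] = List::create(_["dW"] = gfw, _["db"] = gfb);
  NumericMatrix ghw(head.W.n_rows, head.W.n_cols);
  for (size_t j = 0; j < gHeadW.n_elem; ++j) ghw[j] = gHeadW[j];
  NumericVector ghb(1); ghb[0] = gHeadb[0];
  grads["head"] = List::create(_["dW"] = ghw, _["db"] = ghb);

  return List::create(_["loss"] = loss, _["grads"] = grads);
}
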