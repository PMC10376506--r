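// Dense 2-D convolution kernels used by the autodiff layer.
// Array layout everywhere: column-major (H, W, C, N).
// Weight layout: matrix (kh*kw*Cin, Cout) with row index ki + kh*(kj + kw*ci).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat im2col_(const double* x, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad,
                         int Ho, int Wo) {
  arma::mat cols((arma::uword)kh * kw * C, (arma::uword)Ho * Wo * N,
                 arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)H * W * C * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        arma::uword col = (arma::uword)ho + (arma::uword)Ho * (wo + (arma::uword)Wo * n);
        double* dst = cols.colptr(col);
        for (int c = 0; c < C; ++c) {
          const double* xc = xn + (size_t)H * W * c;
          for (int kj = 0; kj < kw; ++kj) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              dst[ki + kh * (kj + kw * c)] = xc[hi + (size_t)H * wi];
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xd,
                             NumericMatrix wmat, int kh, int kw, int cout,
                             int stride, int pad,
                             Nullable<NumericVector> bias) {
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  arma::mat cols = im2col_(REAL(x), H, W, C, N, kh, kw, stride, pad, Ho, Wo);
  arma::mat Wm(wmat.begin(), wmat.nrow(), wmat.ncol(), false, true);
  arma::mat out = Wm.t() * cols;  // (cout, Ho*Wo*N)
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int c = 0; c < cout; ++c) out.row(c) += b[c];
  }
  NumericVector y((R_xlen_t)Ho * Wo * cout * N);
  double* yp = REAL(y);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < cout; ++c) {
      double* dst = yp + (size_t)Ho * Wo * (c + (size_t)cout * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          dst[ho + (size_t)Ho * wo] =
              out(c, (arma::uword)ho + (arma::uword)Ho * (wo + (arma::uword)Wo * n));
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector xd, NumericMatrix wmat,
                    int kh, int kw, int cout, int stride, int pad,
                    NumericVector dy, bool need_dx, bool need_db) {
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  arma::uword M = (arma::uword)Ho * Wo * N;

  arma::mat dYm(cout, M);
  const double* dyp = REAL(dy);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < cout; ++c) {
      const double* src = dyp + (size_t)Ho * Wo * (c + (size_t)cout * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          dYm(c, (arma::uword)ho + (arma::uword)Ho * (wo + (arma::uword)Wo * n)) =
              src[ho + (size_t)Ho * wo];
    }

  arma::mat cols = im2col_(REAL(x), H, W, C, N, kh, kw, stride, pad, Ho, Wo);
  arma::mat dW = cols * dYm.t();  // (kh*kw*C, cout)

  List res;
  res["dw"] = wrap(dW);

  if (need_db) {
    arma::vec db = arma::sum(dYm, 1);
    res["db"] = wrap(db);
  }

  if (need_dx) {
    arma::mat Wm(wmat.begin(), wmat.nrow(), wmat.ncol(), false, true);
    arma::mat dcols = Wm * dYm;  // (kh*kw*C, M)
    NumericVector dx((R_xlen_t)H * W * C * N);
    double* dxp = REAL(dx);
    for (int n = 0; n < N; ++n) {
      double* dxn = dxp + (size_t)H * W * C * n;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          arma::uword col = (arma::uword)ho + (arma::uword)Ho * (wo + (arma::uword)Wo * n);
          const double* src = dcols.colptr(col);
          for (int c = 0; c < C; ++c) {
            double* dxc = dxn + (size_t)H * W * c;
            for (int kj = 0; kj < kw; ++kj) {
              int wi = wo * stride - pad + kj;
              if (wi < 0 || wi >= W) continue;
              for (int ki = 0; ki < kh; ++ki) {
                int hi = ho * stride - pad + ki;
                if (hi < 0 || hi >= H) continue;
                dxc[hi + (size_t)H * wi] += src[ki + kh * (kj + kw * c)];
              }
            }
          }
        }
    }
    dx.attr("dim") = xd;
    res["dx"] = dx;
  }
  return res;
}
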