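// Batched 2-D convolution primitives used by the generator / discriminator
// layers.  Tensors are R arrays with dim = c(C, H, W, N) (channel fastest,
// column-major), weights are matrices of shape Cout x (Cin*k*k) with row
// index r = c + Cin*(ki + k*kj).  Transposed convolution is realised as the
// adjoint of the strided convolution through the same im2col/col2im pair.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_dim(int H, int k, int stride, int pad) {
  return (H + 2 * pad - k) / stride + 1;
}

// cols: (C*k*k) x (Ho*Wo); column p = ho + Ho*wo
static void im2col(const double* x, int C, int H, int W,
                   int k, int stride, int pad, arma::mat& cols) {
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  cols.zeros(C * k * k, Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    const int w0 = wo * stride - pad;
    for (int ho = 0; ho < Ho; ++ho) {
      const int h0 = ho * stride - pad;
      double* dstcol = cols.colptr(ho + Ho * wo);
      for (int kj = 0; kj < k; ++kj) {
        const int w = w0 + kj;
        if (w < 0 || w >= W) continue;
        for (int ki = 0; ki < k; ++ki) {
          const int h = h0 + ki;
          if (h < 0 || h >= H) continue;
          const double* src = x + (std::size_t)C * (h + (std::size_t)H * w);
          std::copy(src, src + C, dstcol + (std::size_t)C * (ki + k * kj));
        }
      }
    }
  }
}

// adjoint of im2col: scatter-add columns back into the (C,H,W) image
static void col2im(const arma::mat& cols, double* x, int C, int H, int W,
                   int k, int stride, int pad) {
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    const int w0 = wo * stride - pad;
    for (int ho = 0; ho < Ho; ++ho) {
      const int h0 = ho * stride - pad;
      const double* srccol = cols.colptr(ho + Ho * wo);
      for (int kj = 0; kj < k; ++kj) {
        const int w = w0 + kj;
        if (w < 0 || w >= W) continue;
        for (int ki = 0; ki < k; ++ki) {
          const int h = h0 + ki;
          if (h < 0 || h >= H) continue;
          double* dst = x + (std::size_t)C * (h + (std::size_t)H * w);
          const double* src = srccol + (std::size_t)C * (ki + k * kj);
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (C,H,W,N) array");
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                           int k, int stride, int pad) {
  IntegerVector d = dims4(x);
  const int C = d[0], H = d[1], W = d[2], N = d[3];
  const int Cout = w.nrow();
  if (w.ncol() != C * k * k) stop("weight shape mismatch");
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("kernel larger than padded input");
  NumericVector y(Cout * (std::size_t)Ho * Wo * N);
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo, N);
  arma::mat wm(w.begin(), Cout, C * k * k, false);
  arma::colvec bv(b.begin(), Cout, false);
  arma::mat cols;
  const std::size_t xs = (std::size_t)C * H * W, ys = (std::size_t)Cout * Ho * Wo;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xs, C, H, W, k, stride, pad, cols);
    arma::mat yn = wm * cols;
    yn.each_col() += bv;
    std::copy(yn.begin(), yn.end(), y.begin() + n * ys);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                  int k, int stride, int pad) {
  IntegerVector d = dims4(x), dd = dims4(dy);
  const int C = d[0], H = d[1], W = d[2], N = d[3];
  const int Cout = dd[0], Ho = dd[1], Wo = dd[2];
  if (dd[3] != N) stop("batch mismatch");
  arma::mat wm(w.begin(), Cout, C * k * k, false);
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  arma::mat dw(Cout, C * k * k, arma::fill::zeros);
  arma::colvec db(Cout, arma::fill::zeros);
  arma::mat cols;
  const std::size_t xs = (std::size_t)C * H * W, ys = (std::size_t)Cout * Ho * Wo;
  for (int n = 0; n < N; ++n) {
    arma::mat dyn(const_cast<double*>(dy.begin()) + n * ys, Cout, Ho * Wo, false);
    im2col(x.begin() + n * xs, C, H, W, k, stride, pad, cols);
    dw += dyn * cols.t();
    db += arma::sum(dyn, 1);
    arma::mat dcols = wm.t() * dyn;
    col2im(dcols, dx.begin() + n * xs, C, H, W, k, stride, pad);
  }
  return List::create(_["dx"] = dx,
                      _["dw"] = NumericMatrix(Cout, C * k * k, dw.begin()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// transposed conv: x has Cin channels, w is Cin x (Cout*k*k),
// output spatial dims Hout x Wout must satisfy out_dim(Hout) == H
// [[Rcpp::export]]
NumericVector cpp_convt_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                            int k, int stride, int pad, int Hout, int Wout) {
  IntegerVector d = dims4(x);
  const int Cin = d[0], H = d[1], W = d[2], N = d[3];
  if (w.nrow() != Cin) stop("weight shape mismatch");
  const int Cout = w.ncol() / (k * k);
  if (out_dim(Hout, k, stride, pad) != H || out_dim(Wout, k, stride, pad) != W)
    stop("inconsistent transposed-conv geometry");
  NumericVector y((std::size_t)Cout * Hout * Wout * N);
  y.attr("dim") = IntegerVector::create(Cout, Hout, Wout, N);
  arma::mat wm(w.begin(), Cin, Cout * k * k, false);
  const std::size_t xs = (std::size_t)Cin * H * W, ys = (std::size_t)Cout * Hout * Wout;
  for (int n = 0; n < N; ++n) {
    arma::mat xn(const_cast<double*>(x.begin()) + n * xs, Cin, H * W, false);
    arma::mat cols = wm.t() * xn;
    double* yn = y.begin() + n * ys;
    col2im(cols, yn, Cout, Hout, Wout, k, stride, pad);
    for (int p = 0; p < Hout * Wout; ++p)
      for (int c = 0; c < Cout; ++c) yn[c + (std::size_t)Cout * p] += b[c];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                   int k, int stride, int pad) {
  IntegerVector d = dims4(x), dd = dims4(dy);
  const int Cin = d[0], H = d[1], W = d[2], N = d[3];
  const int Cout = dd[0], Hout = dd[1], Wout = dd[2];
  arma::mat wm(w.begin(), Cin, Cout * k * k, false);
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  arma::mat dw(Cin, Cout * k * k, arma::fill::zeros);
  arma::colvec db(Cout, arma::fill::zeros);
  arma::mat cols;
  const std::size_t xs = (std::size_t)Cin * H * W, ys = (std::size_t)Cout * Hout * Wout;
  for (int n = 0; n < N; ++n) {
    im2col(dy.begin() + n * ys, Cout, Hout, Wout, k, stride, pad, cols);
    arma::mat xn(const_cast<double*>(x.begin()) + n * xs, Cin, H * W, false);
    arma::mat dxn = wm * cols;
    std::copy(dxn.begin(), dxn.end(), dx.begin() + n * xs);
    dw += xn * cols.t();
    const double* dyn = dy.begin() + n * ys;
    for (int p = 0; p < Hout * Wout; ++p)
      for (int c = 0; c < Cout; ++c) db[c] += dyn[c + (std::size_t)Cout * p];
  }
  return List::create(_["dx"] = dx,
                      _["dw"] = NumericMatrix(Cin, Cout * k * k, dw.begin()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}
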