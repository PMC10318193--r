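// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// All tensors use R's column-major layout.
// Feature tensors: dim (C, H, W)  -> index c + C*(i + H*j)
// Weight banks:    dim (N, M, kh, kw) -> index n + N*(m + M*(p + kh*q))
// Convolution is cross-correlation (no kernel flip), stride 1, zero "same"
// padding; kernel sizes must be odd so the output is centered.
//
// The heavy lifting is done by BLAS via im2col: the padded input patches are
// unrolled into a (M*kh*kw) x (H*W) matrix so the layer forward/backward are
// single matrix products.

static arma::mat im2col_cc(const double* xp, int M, int H, int W, int kh, int kw) {
  const int ph = kh / 2, pw = kw / 2;
  arma::mat C(M * kh * kw, H * W, arma::fill::zeros);
  for (int q = 0; q < kw; ++q) {
    for (int p = 0; p < kh; ++p) {
      const int roff = M * (p + kh * q);
      for (int j = 0; j < W; ++j) {
        const int jj = j + q - pw;
        if (jj < 0 || jj >= W) continue;
        const int i0 = std::max(0, ph - p);          // first valid output row
        const int i1 = std::min(H, H + ph - p);      // one past last valid
        if (i1 <= i0) continue;
        // input rows ii = i + p - ph for i in [i0, i1)
        const double* src = xp + (size_t)M * ((i0 + p - ph) + (size_t)H * jj);
        double* dst = C.colptr(i0 + (size_t)H * j) + roff;
        // copy M*(i1-i0) contiguous doubles: consecutive i are M apart in x
        // and (M*kh*kw) apart in C, so copy column by column
        for (int i = i0; i < i1; ++i) {
          std::memcpy(dst, src, M * sizeof(double));
          src += M;
          dst += C.n_rows;
        }
      }
    }
  }
  return C;
}

// [[Rcpp::export]]
NumericVector cc_conv2d(NumericVector x, NumericVector w, NumericVector b,
                        int M, int H, int W, int N, int kh, int kw) {
  arma::mat C = im2col_cc(x.begin(), M, H, W, kh, kw);
  arma::mat Wm(w.begin(), N, M * kh * kw, false, true);
  arma::colvec bv(b.begin(), N, false, true);
  arma::mat Y = Wm * C;
  Y.each_col() += bv;
  NumericVector y(Y.begin(), Y.end());
  y.attr("dim") = IntegerVector::create(N, H, W);
  return y;
}

// Gradient w.r.t. the input: scatter-add (col2im) of Wm^T * gY.
// [[Rcpp::export]]
NumericVector cc_conv2d_grad_input(NumericVector gy, NumericVector w,
                                   int M, int H, int W, int N, int kh, int kw) {
  const int ph = kh / 2, pw = kw / 2;
  arma::mat Wm(w.begin(), N, M * kh * kw, false, true);
  arma::mat Gy(gy.begin(), N, H * W, false, true);
  arma::mat Gc = Wm.t() * Gy;  // (M*kh*kw) x (H*W)
  NumericVector gx((R_xlen_t)M * H * W);
  double* xp = gx.begin();
  for (int q = 0; q < kw; ++q) {
    for (int p = 0; p < kh; ++p) {
      const int roff = M * (p + kh * q);
      for (int j = 0; j < W; ++j) {
        const int jj = j + q - pw;
        if (jj < 0 || jj >= W) continue;
        const int i0 = std::max(0, ph - p);
        const int i1 = std::min(H, H + ph - p);
        if (i1 <= i0) continue;
        const double* src = Gc.colptr(i0 + (size_t)H * j) + roff;
        double* dst = xp + (size_t)M * ((i0 + p - ph) + (size_t)H * jj);
        for (int i = i0; i < i1; ++i) {
          for (int m = 0; m < M; ++m) dst[m] += src[m];
          src += Gc.n_rows;
          dst += M;
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(M, H, W);
  return gx;
}

// Gradient w.r.t. the weights: gY * im2col(x)^T.
// [[Rcpp::export]]
NumericVector cc_conv2d_grad_weights(NumericVector x, NumericVector gy,
                                     int M, int H, int W, int N, int kh, int kw) {
  arma::mat C = im2col_cc(x.begin(), M, H, W, kh, kw);
  arma::mat Gy(gy.begin(), N, H * W, false, true);
  arma::mat Gw = Gy * C.t();  // N x (M*kh*kw)
  NumericVector gw(Gw.begin(), Gw.end());
  gw.attr("dim") = IntegerVector::create(N, M, kh, kw);
  return gw;
}
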