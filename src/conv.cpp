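// Batched 2-D convolution kernels used by the residual U-Net.
//
// Activation layout: numeric array (H, W, N, C)  -- batch third, channels
// last, so that per-channel statistics (batch norm) reduce to column
// operations on an (H*W*N) x C matrix view.
// Weight layout: (k, k, Cin, Cout); patch vectors are ordered
// (kh, kw, cin) column-major to match matrix(w, k*k*Cin, Cout).
//
// Convolutions use zero padding; the caller passes pad = floor(k/2) for
// "same" spatial arithmetic (Ho = ceil(H/stride) for even H, k = 3).
// im2col/col2im hoist the padding bounds out of the pixel loops and use
// contiguous copies for the stride-1 case, which carries most of the
// network's volume.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int div_ceil_nonneg(int a, int b) {
  return a <= 0 ? 0 : (a + b - 1) / b;
}

// valid output range [lo, hi] for which  o*stride - pad + kk  lies in [0, n)
static inline void valid_range(int n, int k_off, int stride, int pad,
                               int nout, int& lo, int& hi) {
  lo = div_ceil_nonneg(pad - k_off, stride);
  hi = (n - 1 + pad - k_off) / stride;
  if (hi > nout - 1) hi = nout - 1;
}

static void im2col_one(const double* x, int H, int W, R_xlen_t NW, int C,
                       int k, int stride, int pad, int Ho, int Wo,
                       arma::mat& cols) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (R_xlen_t)c * NW;
    for (int kw = 0; kw < k; ++kw) {
      int wo_lo, wo_hi, ho_lo, ho_hi;
      valid_range(W, kw, stride, pad, Wo, wo_lo, wo_hi);
      for (int kh = 0; kh < k; ++kh) {
        valid_range(H, kh, stride, pad, Ho, ho_lo, ho_hi);
        double* dst = cols.colptr(kh + k * kw + k * k * c);
        // zero only the padding borders instead of the whole matrix
        if (wo_lo > 0)
          memset(dst, 0, sizeof(double) * (R_xlen_t)wo_lo * Ho);
        if (wo_hi < Wo - 1)
          memset(dst + (R_xlen_t)(wo_hi + 1) * Ho, 0,
                 sizeof(double) * (R_xlen_t)(Wo - 1 - wo_hi) * Ho);
        for (int wo = wo_lo; wo <= wo_hi; ++wo) {
          double* dcol = dst + (R_xlen_t)wo * Ho;
          if (ho_lo > 0) memset(dcol, 0, sizeof(double) * ho_lo);
          if (ho_hi < Ho - 1)
            memset(dcol + ho_hi + 1, 0, sizeof(double) * (Ho - 1 - ho_hi));
        }
        for (int wo = wo_lo; wo <= wo_hi; ++wo) {
          const int wi = wo * stride - pad + kw;
          const double* src = xc + (R_xlen_t)wi * H + (ho_lo * stride - pad + kh);
          double* d2 = dst + (R_xlen_t)wo * Ho + ho_lo;
          const int len = ho_hi - ho_lo + 1;
          if (stride == 1) {
            memcpy(d2, src, sizeof(double) * len);
          } else {
            for (int i = 0; i < len; ++i) d2[i] = src[(R_xlen_t)i * stride];
          }
        }
      }
    }
  }
}

static void col2im_one(const arma::mat& dcols, double* dxc0, int H, int W,
                       R_xlen_t NW, int C, int k, int stride, int pad,
                       int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* dxc = dxc0 + (R_xlen_t)c * NW;
    for (int kw = 0; kw < k; ++kw) {
      int wo_lo, wo_hi, ho_lo, ho_hi;
      valid_range(W, kw, stride, pad, Wo, wo_lo, wo_hi);
      for (int kh = 0; kh < k; ++kh) {
        valid_range(H, kh, stride, pad, Ho, ho_lo, ho_hi);
        const double* src = dcols.colptr(kh + k * kw + k * k * c);
        for (int wo = wo_lo; wo <= wo_hi; ++wo) {
          const int wi = wo * stride - pad + kw;
          double* d2 = dxc + (R_xlen_t)wi * H + (ho_lo * stride - pad + kh);
          const double* s2 = src + (R_xlen_t)wo * Ho + ho_lo;
          const int len = ho_hi - ho_lo + 1;
          if (stride == 1) {
            for (int i = 0; i < len; ++i) d2[i] += s2[i];
          } else {
            for (int i = 0; i < len; ++i) d2[(R_xlen_t)i * stride] += s2[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], N = xd[2], C = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const R_xlen_t NW = (R_xlen_t)H * W * N;
  const R_xlen_t NWo = (R_xlen_t)Ho * Wo * N;

  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout,
                     false, true);
  const arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);

  NumericVector out((R_xlen_t)Ho * Wo * N * Cout);
  out.attr("dim") = IntegerVector::create(Ho, Wo, N, Cout);

  arma::mat cols(Ho * Wo, k * k * Cin);
  arma::mat o(Ho * Wo, Cout);
  for (int n = 0; n < N; ++n) {
    im2col_one(&x[(R_xlen_t)n * H * W], H, W, NW, C, k, stride, pad,
               Ho, Wo, cols);
    o = cols * Wm;
    o.each_row() += bv;
    for (int co = 0; co < Cout; ++co)
      memcpy(&out[(R_xlen_t)co * NWo + (R_xlen_t)n * Ho * Wo],
             o.colptr(co), sizeof(double) * Ho * Wo);
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dout,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], N = xd[2], C = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const R_xlen_t NW = (R_xlen_t)H * W * N;
  const R_xlen_t NWo = (R_xlen_t)Ho * Wo * N;

  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout,
                     false, true);

  NumericVector dx((R_xlen_t)H * W * N * C);  // zero-initialised
  dx.attr("dim") = IntegerVector::create(H, W, N, C);
  arma::mat dW(k * k * Cin, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);

  arma::mat cols(Ho * Wo, k * k * Cin);
  arma::mat dO(Ho * Wo, Cout);
  arma::mat dcols(Ho * Wo, k * k * Cin);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co)
      memcpy(dO.colptr(co), &dout[(R_xlen_t)co * NWo + (R_xlen_t)n * Ho * Wo],
             sizeof(double) * Ho * Wo);
    im2col_one(&x[(R_xlen_t)n * H * W], H, W, NW, C, k, stride, pad,
               Ho, Wo, cols);
    dW += cols.t() * dO;
    db += arma::sum(dO, 0);
    dcols = dO * Wm.t();
    col2im_one(dcols, &dx[(R_xlen_t)n * H * W], H, W, NW, C, k, stride, pad,
               Ho, Wo);
  }

  NumericVector dWout(dW.begin(), dW.end());
  dWout.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  return List::create(_["dx"] = dx, _["dw"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
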