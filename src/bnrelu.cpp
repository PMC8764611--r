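// Fused batch-norm + ReLU kernels. Activations are (H, W, N, C) arrays,
// viewed here as an (m x C) matrix with m = H*W*N, so per-channel
// statistics are column reductions. Fusing the two ops avoids the large
// intermediate temporaries an R-level implementation would allocate in the
// training inner loop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List bnrelu_fwd_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                    NumericVector rmean, NumericVector rvar, double momentum,
                    double eps, bool training) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[3];
  const R_xlen_t m = (R_xlen_t)xd[0] * xd[1] * xd[2];
  NumericVector out(x.size());
  out.attr("dim") = xd;
  NumericVector mu(C), invsd(C);
  NumericVector nrmean = clone(rmean), nrvar = clone(rvar);

  for (int c = 0; c < C; ++c) {
    const double* xc = &x[m * c];
    double* oc = &out[m * c];
    double mc, vc;
    if (training) {
      double s = 0.0;
      for (R_xlen_t i = 0; i < m; ++i) s += xc[i];
      mc = s / m;
      double ss = 0.0;
      for (R_xlen_t i = 0; i < m; ++i) {
        double d = xc[i] - mc;
        ss += d * d;
      }
      vc = ss / m;  // biased batch variance
      nrmean[c] = momentum * nrmean[c] + (1 - momentum) * mc;
      nrvar[c] = momentum * nrvar[c] + (1 - momentum) * vc;
    } else {
      mc = rmean[c];
      vc = rvar[c];
    }
    const double isd = 1.0 / std::sqrt(vc + eps);
    mu[c] = mc;
    invsd[c] = isd;
    const double a = gamma[c] * isd;
    const double b = beta[c] - a * mc;
    for (R_xlen_t i = 0; i < m; ++i) {
      double v = a * xc[i] + b;
      oc[i] = v > 0 ? v : 0.0;
    }
  }
  return List::create(_["r"] = out, _["mu"] = mu, _["invsd"] = invsd,
                      _["rmean"] = nrmean, _["rvar"] = nrvar);
}

// Backward through ReLU then batch norm (training statistics).
// dr: gradient at the ReLU output; x: BN input; r: ReLU output (its
// positivity is the ReLU mask).
// [[Rcpp::export]]
List bnrelu_bwd_cpp(NumericVector dr, NumericVector x, NumericVector r,
                    NumericVector mu, NumericVector invsd,
                    NumericVector gamma) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[3];
  const R_xlen_t m = (R_xlen_t)xd[0] * xd[1] * xd[2];
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);

  for (int c = 0; c < C; ++c) {
    const double* drc = &dr[m * c];
    const double* xc = &x[m * c];
    const double* rc = &r[m * c];
    double* dxc = &dx[m * c];
    const double mc = mu[c], isd = invsd[c], g = gamma[c];
    double s_d = 0.0, s_dx = 0.0, s_g = 0.0;
    for (R_xlen_t i = 0; i < m; ++i) {
      const double d = rc[i] > 0 ? drc[i] : 0.0;  // ReLU gate
      const double xhat = (xc[i] - mc) * isd;
      s_d += d;
      s_g += d * xhat;
      (void)s_dx;
      dxc[i] = d;  // stash gated gradient; finished below
    }
    dgamma[c] = s_g;
    dbeta[c] = s_d;
    const double mean_d = s_d / m, mean_dx = s_g / m;
    for (R_xlen_t i = 0; i < m; ++i) {
      const double xhat = (xc[i] - mc) * isd;
      dxc[i] = (dxc[i] * g - mean_d * g - xhat * mean_dx * g) * isd;
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
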