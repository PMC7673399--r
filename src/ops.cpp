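// Batch normalization and activation kernels (channel axis fastest).

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// x viewed as (C, M); returns y plus per-channel batch mean/var.
// [[Rcpp::export(name = ".bn_fwd")]]
List bn_fwd(NumericVector x, int C, NumericVector gamma,
            NumericVector beta, double eps) {
  const R_xlen_t M = x.size() / C;
  NumericVector mean(C), var(C);
  const double* xp = x.begin();
  for (R_xlen_t j = 0; j < M; ++j) {
    const double* col = xp + j * C;
    for (int c = 0; c < C; ++c) mean[c] += col[c];
  }
  for (int c = 0; c < C; ++c) mean[c] /= M;
  for (R_xlen_t j = 0; j < M; ++j) {
    const double* col = xp + j * C;
    for (int c = 0; c < C; ++c) {
      const double d = col[c] - mean[c];
      var[c] += d * d;
    }
  }
  for (int c = 0; c < C; ++c) var[c] /= M;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  std::vector<double> a(C), b(C);
  for (int c = 0; c < C; ++c) {
    a[c] = gamma[c] / std::sqrt(var[c] + eps);
    b[c] = beta[c] - a[c] * mean[c];
  }
  double* yp = y.begin();
  for (R_xlen_t j = 0; j < M; ++j) {
    const double* col = xp + j * C;
    double* ycol = yp + j * C;
    for (int c = 0; c < C; ++c) ycol[c] = a[c] * col[c] + b[c];
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var);
}

// eval-mode affine transform with running statistics
// [[Rcpp::export(name = ".bn_eval")]]
NumericVector bn_eval(NumericVector x, int C, NumericVector gamma,
                      NumericVector beta, NumericVector rmean,
                      NumericVector rvar, double eps) {
  const R_xlen_t M = x.size() / C;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  std::vector<double> a(C), b(C);
  for (int c = 0; c < C; ++c) {
    a[c] = gamma[c] / std::sqrt(rvar[c] + eps);
    b[c] = beta[c] - a[c] * rmean[c];
  }
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t j = 0; j < M; ++j)
    for (int c = 0; c < C; ++c) yp[j * C + c] = a[c] * xp[j * C + c] + b[c];
  return y;
}

// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericVector x, NumericVector dy, int C, NumericVector gamma,
            NumericVector mean, NumericVector var, double eps) {
  const R_xlen_t M = x.size() / C;
  NumericVector dgamma(C), dbeta(C);
  std::vector<double> invstd(C), sxh(C, 0.0), sdy(C, 0.0);
  for (int c = 0; c < C; ++c) invstd[c] = 1.0 / std::sqrt(var[c] + eps);
  const double* xp = x.begin();
  const double* dp = dy.begin();
  for (R_xlen_t j = 0; j < M; ++j) {
    const double* xc = xp + j * C;
    const double* dc = dp + j * C;
    for (int c = 0; c < C; ++c) {
      const double xhat = (xc[c] - mean[c]) * invstd[c];
      dgamma[c] += dc[c] * xhat;
      dbeta[c] += dc[c];
    }
  }
  for (int c = 0; c < C; ++c) {
    sxh[c] = dgamma[c] / M;      // mean of dy * xhat
    sdy[c] = dbeta[c] / M;       // mean of dy
  }
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  double* dxp = dx.begin();
  for (R_xlen_t j = 0; j < M; ++j) {
    const double* xc = xp + j * C;
    const double* dc = dp + j * C;
    double* oc = dxp + j * C;
    for (int c = 0; c < C; ++c) {
      const double xhat = (xc[c] - mean[c]) * invstd[c];
      oc[c] = gamma[c] * invstd[c] * (dc[c] - sdy[c] - xhat * sxh[c]);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".relu_fwd")]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return y;
}

// backward uses the forward output: x > 0 iff y > 0
// [[Rcpp::export(name = ".relu_bwd")]]
NumericVector relu_bwd(NumericVector y, NumericVector dy) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[i] = y[i] > 0 ? dy[i] : 0.0;
  return dx;
}

// [[Rcpp::export(name = ".elu_fwd")]]
NumericVector elu_fwd(NumericVector x, double alpha) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] > 0 ? x[i] : alpha * (std::exp(x[i]) - 1.0);
  return y;
}

// ELU preserves sign, so the forward output determines the region
// [[Rcpp::export(name = ".elu_bwd")]]
NumericVector elu_bwd(NumericVector y, NumericVector dy, double alpha) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dx[i] = y[i] > 0 ? dy[i] : dy[i] * (y[i] + alpha);
  return dx;
}
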