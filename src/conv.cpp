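// Batched 2-D convolution primitives.
//
// Tensor layout is column-major with the channel axis fastest:
//   x    : (C_in,  H,  W,  N)
//   out  : (C_out, OH, OW, N)
//   Wm   : (C_in*KH*KW, C_out), patch rows ordered channel-fastest, then
//          kh, then kw (so rows for tap (kh,kw) are a contiguous C_in block)
//
// The networks here use long 1-D kernels on small channel counts, where
// im2col's K-fold data expansion is memory-bound. Instead the convolution
// is evaluated tap by tap: for each kernel offset one (C_out x C_in) gemm
// (dgemm, beta = 1, lda tricks select the tap's weight block in place) is
// accumulated over the shifted input slab. The W axis is processed in
// tiles sized to keep the input/output working set inside L2 across all
// taps. Fast paths:
//   - 1x1 kernel, unit stride: one whole-batch gemm
//   - full-extent valid kernel along H (KH == H, PH == 0): one whole-batch
//     gemm on the (C*H, W*N) view
//   - kernel along W (KH == 1, SH == 1, PH == 0): tiled slab gemms
//     (gathered when the temporal stride exceeds 1)
//   - kernel along H (KW == 1, SW == 1, SH == 1): tiled gather/scatter of
//     per-column runs
// plus a generic per-column fallback for arbitrary kernels.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <vector>
#include <cstring>
#include <algorithm>

using namespace Rcpp;

static void gemm(bool ta, bool tb, int m, int n, int k, double alpha,
                 const double* A, int lda, const double* B, int ldb,
                 double beta, double* C, int ldc) {
  const char* TA = ta ? "T" : "N";
  const char* TB = tb ? "T" : "N";
  F77_CALL(dgemm)(TA, TB, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta,
                  C, &ldc FCONE FCONE);
}

struct Dims {
  int C, H, W, N, Cout, KH, KW, SH, SW, PH, PW, OH, OW;
};

struct Tap {
  int kh, kw, off;            // off: first row of the tap's weight block
  int oh0, oh1, ow0, ow1;     // valid output ranges
};

static Dims mkdims(IntegerVector xdim, int Cout, int KH, int KW,
                   int SH, int SW, int PH, int PW) {
  Dims d;
  d.C = xdim[0]; d.H = xdim[1]; d.W = xdim[2]; d.N = xdim[3];
  d.Cout = Cout; d.KH = KH; d.KW = KW; d.SH = SH; d.SW = SW;
  d.PH = PH; d.PW = PW;
  d.OH = (d.H + 2 * d.PH - d.KH) / d.SH + 1;
  d.OW = (d.W + 2 * d.PW - d.KW) / d.SW + 1;
  if (d.OH < 1 || d.OW < 1) stop("convolution output would be empty");
  return d;
}

static inline void taprange(int k, int S, int P, int in, int out,
                            int& o0, int& o1) {
  o0 = 0;
  while (o0 < out && (o0 * S - P + k) < 0) ++o0;
  o1 = out - 1;
  while (o1 >= 0 && (o1 * S - P + k) >= in) --o1;
}

static std::vector<Tap> mktaps(const Dims& d) {
  std::vector<Tap> taps;
  for (int kw = 0; kw < d.KW; ++kw) {
    Tap t;
    taprange(kw, d.SW, d.PW, d.W, d.OW, t.ow0, t.ow1);
    if (t.ow1 < t.ow0) continue;
    for (int kh = 0; kh < d.KH; ++kh) {
      taprange(kh, d.SH, d.PH, d.H, d.OH, t.oh0, t.oh1);
      if (t.oh1 < t.oh0) continue;
      t.kh = kh; t.kw = kw;
      t.off = d.C * (kh + d.KH * kw);
      taps.push_back(t);
    }
  }
  return taps;
}

// tile width along the (output) W axis so C*H*tile stays around 128 KB
static int tilew(const Dims& d) {
  const double target = 16384.0;           // doubles
  int tw = (int)(target / ((double)d.C * d.H));
  return std::max(8, std::min(tw, d.OW));
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, IntegerVector xdim,
                         NumericMatrix Wm, NumericVector bias,
                         int KH, int KW, int SH, int SW, int PH, int PW) {
  const Dims d = mkdims(xdim, Wm.ncol(), KH, KW, SH, SW, PH, PW);
  const int K = d.C * d.KH * d.KW;
  if (Wm.nrow() != K) stop("weight rows do not match C*KH*KW");

  NumericVector out(R_xlen_t(d.Cout) * d.OH * d.OW * d.N);
  out.attr("dim") = IntegerVector::create(d.Cout, d.OH, d.OW, d.N);
  {
    double* op = out.begin();
    const R_xlen_t cols = R_xlen_t(d.OH) * d.OW * d.N;
    for (R_xlen_t j = 0; j < cols; ++j)
      for (int c = 0; c < d.Cout; ++c) op[j * d.Cout + c] = bias[c];
  }
  const double* W = Wm.begin();

  if ((d.KH == 1 && d.KW == 1 && d.SH == 1 && d.SW == 1) ||
      (d.KH == d.H && d.PH == 0 && d.KW == 1 && d.SW == 1)) {
    const int rows = d.C * d.KH;
    const R_xlen_t cols = x.size() / rows;
    gemm(true, false, d.Cout, (int)cols, rows, 1.0, W, K,
         x.begin(), rows, 1.0, out.begin(), d.Cout);
    return out;
  }

  const std::vector<Tap> taps = mktaps(d);
  const R_xlen_t xstep = R_xlen_t(d.C) * d.H * d.W;
  const R_xlen_t ostep = R_xlen_t(d.Cout) * d.OH * d.OW;
  const int TW = tilew(d);
  std::vector<double> buf, tmp;
  for (int n = 0; n < d.N; ++n) {
    const double* xp = x.begin() + xstep * n;
    double* op = out.begin() + ostep * n;
    for (int t0 = 0; t0 < d.OW; t0 += TW) {
      const int t1 = std::min(t0 + TW, d.OW) - 1;
      for (const Tap& t : taps) {
        const int a = std::max(t.ow0, t0), b = std::min(t.ow1, t1);
        if (b < a) continue;
        const int now = b - a + 1;
        if (d.KH == 1 && d.SH == 1 && d.PH == 0) {    // kernel along W
          double* yp = op + R_xlen_t(d.Cout) * d.OH * a;
          if (d.SW == 1) {
            const int w0 = a - d.PW + t.kw;
            gemm(true, false, d.Cout, d.H * now, d.C, 1.0, W + t.off, K,
                 xp + R_xlen_t(d.C) * d.H * w0, d.C, 1.0, yp, d.Cout);
          } else {
            buf.resize((size_t)d.C * d.H * now);
            for (int j = 0; j < now; ++j) {
              const int w = (a + j) * d.SW - d.PW + t.kw;
              std::memcpy(buf.data() + (size_t)d.C * d.H * j,
                          xp + R_xlen_t(d.C) * d.H * w,
                          sizeof(double) * d.C * d.H);
            }
            gemm(true, false, d.Cout, d.H * now, d.C, 1.0, W + t.off, K,
                 buf.data(), d.C, 1.0, yp, d.Cout);
          }
        } else if (d.KW == 1 && d.SW == 1 && d.PW == 0 && d.SH == 1) {
          const int len = t.oh1 - t.oh0 + 1;          // kernel along H
          const int h0 = t.oh0 - d.PH + t.kh;
          buf.resize((size_t)d.C * len * now);
          for (int j = 0; j < now; ++j)
            std::memcpy(buf.data() + (size_t)d.C * len * j,
                        xp + d.C * (R_xlen_t(h0) + R_xlen_t(d.H) * (a + j)),
                        sizeof(double) * d.C * len);
          tmp.resize((size_t)d.Cout * len * now);
          gemm(true, false, d.Cout, len * now, d.C, 1.0, W + t.off, K,
               buf.data(), d.C, 0.0, tmp.data(), d.Cout);
          for (int j = 0; j < now; ++j) {
            double* dst = op + d.Cout * (R_xlen_t(t.oh0) +
                                         R_xlen_t(d.OH) * (a + j));
            const double* src = tmp.data() + (size_t)d.Cout * len * j;
            const int m = d.Cout * len;
            for (int i = 0; i < m; ++i) dst[i] += src[i];
          }
        } else {                                      // generic fallback
          for (int ow = a; ow <= b; ++ow) {
            const int w = ow * d.SW - d.PW + t.kw;
            for (int oh = t.oh0; oh <= t.oh1; ++oh) {
              const int h = oh * d.SH - d.PH + t.kh;
              const double* src = xp + d.C * (R_xlen_t(h) +
                                              R_xlen_t(d.H) * w);
              double* dst = op + d.Cout * (R_xlen_t(oh) +
                                           R_xlen_t(d.OH) * ow);
              for (int co = 0; co < d.Cout; ++co) {
                const double* wcol = W + t.off + (size_t)K * co;
                double acc = 0;
                for (int c = 0; c < d.C; ++c) acc += wcol[c] * src[c];
                dst[co] += acc;
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, IntegerVector xdim,
                NumericMatrix Wm, NumericVector dout,
                int KH, int KW, int SH, int SW, int PH, int PW) {
  const Dims d = mkdims(xdim, Wm.ncol(), KH, KW, SH, SW, PH, PW);
  const int K = d.C * d.KH * d.KW;

  NumericVector dx(x.size());
  dx.attr("dim") = xdim;
  NumericMatrix dW(K, d.Cout);
  NumericVector db(d.Cout);
  {
    const double* dp = dout.begin();
    const R_xlen_t cols = R_xlen_t(d.OH) * d.OW * d.N;
    for (R_xlen_t j = 0; j < cols; ++j)
      for (int c = 0; c < d.Cout; ++c) db[c] += dp[j * d.Cout + c];
  }
  const double* W = Wm.begin();

  if ((d.KH == 1 && d.KW == 1 && d.SH == 1 && d.SW == 1) ||
      (d.KH == d.H && d.PH == 0 && d.KW == 1 && d.SW == 1)) {
    const int rows = d.C * d.KH;
    const R_xlen_t cols = x.size() / rows;
    gemm(false, false, rows, (int)cols, d.Cout, 1.0, W, K,
         dout.begin(), d.Cout, 1.0, dx.begin(), rows);
    gemm(false, true, rows, d.Cout, (int)cols, 1.0, x.begin(), rows,
         dout.begin(), d.Cout, 1.0, dW.begin(), K);
    return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
  }

  const std::vector<Tap> taps = mktaps(d);
  const R_xlen_t xstep = R_xlen_t(d.C) * d.H * d.W;
  const R_xlen_t ostep = R_xlen_t(d.Cout) * d.OH * d.OW;
  const int TW = tilew(d);
  std::vector<double> buf, dbuf;
  std::vector<double> dwt((size_t)d.C * d.Cout * taps.size(), 0.0);
  for (int n = 0; n < d.N; ++n) {
    const double* xp = x.begin() + xstep * n;
    double* dxp = dx.begin() + xstep * n;
    const double* dop = dout.begin() + ostep * n;
    for (int t0 = 0; t0 < d.OW; t0 += TW) {
      const int t1 = std::min(t0 + TW, d.OW) - 1;
      for (size_t ti = 0; ti < taps.size(); ++ti) {
        const Tap& t = taps[ti];
        const int a = std::max(t.ow0, t0), b = std::min(t.ow1, t1);
        if (b < a) continue;
        const int now = b - a + 1;
        double* dwp = dwt.data() + (size_t)d.C * d.Cout * ti;
        if (d.KH == 1 && d.SH == 1 && d.PH == 0) {
          const double* dyp = dop + R_xlen_t(d.Cout) * d.OH * a;
          if (d.SW == 1) {
            const int w0 = a - d.PW + t.kw;
            const double* xs = xp + R_xlen_t(d.C) * d.H * w0;
            double* dxs = dxp + R_xlen_t(d.C) * d.H * w0;
            gemm(false, true, d.C, d.Cout, d.H * now, 1.0, xs, d.C,
                 dyp, d.Cout, 1.0, dwp, d.C);
            gemm(false, false, d.C, d.H * now, d.Cout, 1.0, W + t.off, K,
                 dyp, d.Cout, 1.0, dxs, d.C);
          } else {
            buf.resize((size_t)d.C * d.H * now);
            for (int j = 0; j < now; ++j) {
              const int w = (a + j) * d.SW - d.PW + t.kw;
              std::memcpy(buf.data() + (size_t)d.C * d.H * j,
                          xp + R_xlen_t(d.C) * d.H * w,
                          sizeof(double) * d.C * d.H);
            }
            gemm(false, true, d.C, d.Cout, d.H * now, 1.0, buf.data(),
                 d.C, dyp, d.Cout, 1.0, dwp, d.C);
            gemm(false, false, d.C, d.H * now, d.Cout, 1.0, W + t.off, K,
                 dyp, d.Cout, 0.0, buf.data(), d.C);
            for (int j = 0; j < now; ++j) {
              const int w = (a + j) * d.SW - d.PW + t.kw;
              double* dst = dxp + R_xlen_t(d.C) * d.H * w;
              const double* src = buf.data() + (size_t)d.C * d.H * j;
              const int m = d.C * d.H;
              for (int i = 0; i < m; ++i) dst[i] += src[i];
            }
          }
        } else if (d.KW == 1 && d.SW == 1 && d.PW == 0 && d.SH == 1) {
          const int len = t.oh1 - t.oh0 + 1;
          const int h0 = t.oh0 - d.PH + t.kh;
          buf.resize((size_t)d.C * len * now);
          dbuf.resize((size_t)d.Cout * len * now);
          for (int j = 0; j < now; ++j) {
            std::memcpy(buf.data() + (size_t)d.C * len * j,
                        xp + d.C * (R_xlen_t(h0) + R_xlen_t(d.H) * (a + j)),
                        sizeof(double) * d.C * len);
            std::memcpy(dbuf.data() + (size_t)d.Cout * len * j,
                        dop + d.Cout * (R_xlen_t(t.oh0) +
                                        R_xlen_t(d.OH) * (a + j)),
                        sizeof(double) * d.Cout * len);
          }
          gemm(false, true, d.C, d.Cout, len * now, 1.0, buf.data(), d.C,
               dbuf.data(), d.Cout, 1.0, dwp, d.C);
          gemm(false, false, d.C, len * now, d.Cout, 1.0, W + t.off, K,
               dbuf.data(), d.Cout, 0.0, buf.data(), d.C);
          for (int j = 0; j < now; ++j) {
            double* dst = dxp + d.C * (R_xlen_t(h0) +
                                       R_xlen_t(d.H) * (a + j));
            const double* src = buf.data() + (size_t)d.C * len * j;
            const int m = d.C * len;
            for (int i = 0; i < m; ++i) dst[i] += src[i];
          }
        } else {
          for (int ow = a; ow <= b; ++ow) {
            const int w = ow * d.SW - d.PW + t.kw;
            for (int oh = t.oh0; oh <= t.oh1; ++oh) {
              const int h = oh * d.SH - d.PH + t.kh;
              const double* src = xp + d.C * (R_xlen_t(h) +
                                              R_xlen_t(d.H) * w);
              double* dst = dxp + d.C * (R_xlen_t(h) +
                                         R_xlen_t(d.H) * w);
              const double* dg = dop + d.Cout * (R_xlen_t(oh) +
                                                 R_xlen_t(d.OH) * ow);
              for (int co = 0; co < d.Cout; ++co) {
                const double g = dg[co];
                const double* wcol = W + t.off + (size_t)K * co;
                double* dwcol = dwp + (size_t)d.C * co;
                for (int c = 0; c < d.C; ++c) {
                  dwcol[c] += src[c] * g;
                  dst[c] += wcol[c] * g;
                }
              }
            }
          }
        }
      }
    }
  }
  for (size_t ti = 0; ti < taps.size(); ++ti) {
    const Tap& t = taps[ti];
    const double* dwp = dwt.data() + (size_t)d.C * d.Cout * ti;
    for (int co = 0; co < d.Cout; ++co)
      for (int c = 0; c < d.C; ++c)
        dW[(size_t)t.off + c + (size_t)K * co] +=
          dwp[(size_t)c + (size_t)d.C * co];
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
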