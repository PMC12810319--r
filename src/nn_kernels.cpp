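// Dense compute kernels for the CNN quality regressor.
//
// Tensors are R arrays in column-major (H, W, C, N) layout; convolution
// weights are (kh, kw, Cin, Cout). Convolutions are computed directly
// (no im2col materialization) over a per-image zero-padded buffer, with
// the innermost loop running down contiguous output rows so the compiler
// can vectorize it. Batch norm uses biased batch variance, matching the
// usual deep-learning convention.

#include <Rcpp.h>
#include <vector>
#include <cstring>

using namespace Rcpp;

static inline void getDims4(const NumericVector& x, int* d) {
  IntegerVector dv = x.attr("dim");
  if (dv.size() != 4) stop("expected a 4D array");
  for (int k = 0; k < 4; ++k) d[k] = dv[k];
}

static void padImage(const double* x, double* xpad, int H, int W, int C,
                     int pad) {
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  std::memset(xpad, 0, sizeof(double) * (size_t)Hp * Wp * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    double* pc = xpad + (size_t)c * Hp * Wp;
    for (int j = 0; j < W; ++j) {
      std::memcpy(pc + (size_t)(j + pad) * Hp + pad, xc + (size_t)j * H,
                  sizeof(double) * H);
    }
  }
}

// [[Rcpp::export]]
NumericVector cs_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                          int stride, int pad) {
  int xd[4], wd[4];
  getDims4(x, xd);
  getDims4(w, wd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("input channels do not match weights");
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int Ho = (Hp - kh) / stride + 1, Wo = (Wp - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("output size would be empty");
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  std::vector<double> xpad((size_t)Hp * Wp * C);
  const double* xp0 = REAL(x);
  const double* wp = REAL(w);
  const double* bp = REAL(b);
  double* yp0 = REAL(y);
  for (int n = 0; n < N; ++n) {
    padImage(xp0 + (size_t)n * H * W * C, xpad.data(), H, W, C, pad);
    for (int co = 0; co < Cout; ++co) {
      double* yc = yp0 + ((size_t)n * Cout + co) * Ho * Wo;
      for (int t = 0; t < Ho * Wo; ++t) yc[t] = bp[co];
      for (int ci = 0; ci < C; ++ci) {
        const double* pc = xpad.data() + (size_t)ci * Hp * Wp;
        for (int kj = 0; kj < kw; ++kj) {
          for (int ki = 0; ki < kh; ++ki) {
            const double wv = wp[ki + kh * (kj + kw * (ci + (size_t)Cin * co))];
            for (int oj = 0; oj < Wo; ++oj) {
              const double* __restrict__ src = pc + (size_t)(oj * stride + kj) * Hp + ki;
              double* __restrict__ dst = yc + (size_t)oj * Ho;
              if (stride == 1) {
                for (int oi = 0; oi < Ho; ++oi) dst[oi] += wv * src[oi];
              } else {
                for (int oi = 0; oi < Ho; ++oi) dst[oi] += wv * src[oi * stride];
              }
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cs_conv_bwd(NumericVector x, NumericVector w, NumericVector gy,
                 int stride, int pad) {
  int xd[4], wd[4], gd[4];
  getDims4(x, xd);
  getDims4(w, wd);
  getDims4(gy, gd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  if (gd[2] != Cout || gd[3] != N) stop("gradient dims mismatch");
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gw((R_xlen_t)kh * kw * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  NumericVector gb(Cout);
  std::vector<double> xpad((size_t)Hp * Wp * C);
  std::vector<double> gxpad((size_t)Hp * Wp * C);
  const double* xp0 = REAL(x);
  const double* wp = REAL(w);
  const double* gyp0 = REAL(gy);
  double* gxp0 = REAL(gx);
  double* gwp = REAL(gw);
  double* gbp = REAL(gb);
  for (int n = 0; n < N; ++n) {
    padImage(xp0 + (size_t)n * H * W * C, xpad.data(), H, W, C, pad);
    std::memset(gxpad.data(), 0, sizeof(double) * gxpad.size());
    for (int co = 0; co < Cout; ++co) {
      const double* gyc = gyp0 + ((size_t)n * Cout + co) * Ho * Wo;
      double s = 0.0;
      for (int t = 0; t < Ho * Wo; ++t) s += gyc[t];
      gbp[co] += s;
      for (int ci = 0; ci < C; ++ci) {
        const double* pc = xpad.data() + (size_t)ci * Hp * Wp;
        double* gpc = gxpad.data() + (size_t)ci * Hp * Wp;
        for (int kj = 0; kj < kw; ++kj) {
          for (int ki = 0; ki < kh; ++ki) {
            const size_t widx = ki + kh * (kj + kw * (ci + (size_t)Cin * co));
            const double wv = wp[widx];
            double acc = 0.0;
            for (int oj = 0; oj < Wo; ++oj) {
              const double* __restrict__ src = pc + (size_t)(oj * stride + kj) * Hp + ki;
              double* __restrict__ gdst = gpc + (size_t)(oj * stride + kj) * Hp + ki;
              const double* __restrict__ g = gyc + (size_t)oj * Ho;
              if (stride == 1) {
                for (int oi = 0; oi < Ho; ++oi) {
                  acc += g[oi] * src[oi];
                  gdst[oi] += wv * g[oi];
                }
              } else {
                for (int oi = 0; oi < Ho; ++oi) {
                  acc += g[oi] * src[oi * stride];
                  gdst[oi * stride] += wv * g[oi];
                }
              }
            }
            gwp[widx] += acc;
          }
        }
      }
    }
    // crop padded input gradient back to (H, W, C)
    double* gxn = gxp0 + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      const double* gpc = gxpad.data() + (size_t)c * Hp * Wp;
      double* gxc = gxn + (size_t)c * H * W;
      for (int j = 0; j < W; ++j) {
        std::memcpy(gxc + (size_t)j * H, gpc + (size_t)(j + pad) * Hp + pad,
                    sizeof(double) * H);
      }
    }
  }
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// [[Rcpp::export]]
List cs_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
               double eps, bool useStats, NumericVector mean_,
               NumericVector var_) {
  int xd[4];
  getDims4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t plane = (size_t)H * W;
  NumericVector y((R_xlen_t)H * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector mu(C), vr(C);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  const double M = (double)plane * N;
  if (useStats) {
    for (int c = 0; c < C; ++c) { mu[c] = mean_[c]; vr[c] = var_[c]; }
  } else {
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xc = xp + ((size_t)n * C + c) * plane;
        for (size_t t = 0; t < plane; ++t) { s += xc[t]; s2 += xc[t] * xc[t]; }
      }
      mu[c] = s / M;
      vr[c] = s2 / M - mu[c] * mu[c];
      if (vr[c] < 0) vr[c] = 0;
    }
  }
  for (int c = 0; c < C; ++c) {
    const double istd = 1.0 / std::sqrt(vr[c] + eps);
    const double a = gamma[c] * istd;
    const double b0 = beta[c] - a * mu[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = xp + ((size_t)n * C + c) * plane;
      double* yc = yp + ((size_t)n * C + c) * plane;
      for (size_t t = 0; t < plane; ++t) yc[t] = a * xc[t] + b0;
    }
  }
  return List::create(Named("y") = y, Named("mean") = mu, Named("var") = vr);
}

// [[Rcpp::export]]
List cs_bn_bwd(NumericVector x, NumericVector gy, NumericVector gamma,
               NumericVector mean_, NumericVector var_, double eps) {
  int xd[4];
  getDims4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t plane = (size_t)H * W;
  const double M = (double)plane * N;
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector ggamma(C), gbeta(C);
  const double* xp = REAL(x);
  const double* gp = REAL(gy);
  double* gxp = REAL(gx);
  for (int c = 0; c < C; ++c) {
    const double mu = mean_[c];
    const double istd = 1.0 / std::sqrt(var_[c] + eps);
    double sg = 0.0, sgx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = xp + ((size_t)n * C + c) * plane;
      const double* gc = gp + ((size_t)n * C + c) * plane;
      for (size_t t = 0; t < plane; ++t) {
        sg += gc[t];
        sgx += gc[t] * (xc[t] - mu) * istd;
      }
    }
    gbeta[c] = sg;
    ggamma[c] = sgx;
    const double k = gamma[c] * istd / M;
    for (int n = 0; n < N; ++n) {
      const double* xc = xp + ((size_t)n * C + c) * plane;
      const double* gc = gp + ((size_t)n * C + c) * plane;
      double* gxc = gxp + ((size_t)n * C + c) * plane;
      for (size_t t = 0; t < plane; ++t) {
        const double xhat = (xc[t] - mu) * istd;
        gxc[t] = k * (M * gc[t] - sg - xhat * sgx);
      }
    }
  }
  return List::create(Named("gx") = gx, Named("ggamma") = ggamma,
                      Named("gbeta") = gbeta);
}

// [[Rcpp::export]]
NumericVector cs_relu_fwd(NumericVector x) {
  NumericVector y = clone(x);
  double* yp = REAL(y);
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i) if (yp[i] < 0) yp[i] = 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cs_relu_bwd(NumericVector y, NumericVector gy) {
  NumericVector gx = clone(gy);
  const double* yp = REAL(y);
  double* gp = REAL(gx);
  const R_xlen_t n = gx.size();
  for (R_xlen_t i = 0; i < n; ++i) if (yp[i] <= 0) gp[i] = 0;
  return gx;
}

// fused batch norm + ReLU (training mode): avoids materializing the
// intermediate normalized tensor and the separate ReLU mask
// [[Rcpp::export]]
List cs_bnrelu_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                   double eps, bool useStats, NumericVector mean_,
                   NumericVector var_) {
  int xd[4];
  getDims4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t plane = (size_t)H * W;
  NumericVector y((R_xlen_t)H * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector mu(C), vr(C);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  const double M = (double)plane * N;
  if (useStats) {
    for (int c = 0; c < C; ++c) { mu[c] = mean_[c]; vr[c] = var_[c]; }
  } else {
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xc = xp + ((size_t)n * C + c) * plane;
        for (size_t t = 0; t < plane; ++t) { s += xc[t]; s2 += xc[t] * xc[t]; }
      }
      mu[c] = s / M;
      vr[c] = s2 / M - mu[c] * mu[c];
      if (vr[c] < 0) vr[c] = 0;
    }
  }
  for (int c = 0; c < C; ++c) {
    const double istd = 1.0 / std::sqrt(vr[c] + eps);
    const double a = gamma[c] * istd;
    const double b0 = beta[c] - a * mu[c];
    for (int n = 0; n < N; ++n) {
      const double* __restrict__ xc = xp + ((size_t)n * C + c) * plane;
      double* __restrict__ yc = yp + ((size_t)n * C + c) * plane;
      for (size_t t = 0; t < plane; ++t) {
        const double v = a * xc[t] + b0;
        yc[t] = v > 0 ? v : 0;
      }
    }
  }
  return List::create(Named("y") = y, Named("mean") = mu, Named("var") = vr);
}

// [[Rcpp::export]]
List cs_bnrelu_bwd(NumericVector x, NumericVector gy, NumericVector gamma,
                   NumericVector beta, NumericVector mean_,
                   NumericVector var_, double eps) {
  int xd[4];
  getDims4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t plane = (size_t)H * W;
  const double M = (double)plane * N;
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector ggamma(C), gbeta(C);
  const double* xp = REAL(x);
  const double* gp = REAL(gy);
  double* gxp = REAL(gx);
  for (int c = 0; c < C; ++c) {
    const double mu = mean_[c];
    const double istd = 1.0 / std::sqrt(var_[c] + eps);
    const double a = gamma[c] * istd;
    const double b0 = beta[c] - a * mu;
    double sg = 0.0, sgx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* __restrict__ xc = xp + ((size_t)n * C + c) * plane;
      const double* __restrict__ gc = gp + ((size_t)n * C + c) * plane;
      for (size_t t = 0; t < plane; ++t) {
        const double act = a * xc[t] + b0;
        const double g = act > 0 ? gc[t] : 0.0;
        sg += g;
        sgx += g * (xc[t] - mu) * istd;
      }
    }
    gbeta[c] = sg;
    ggamma[c] = sgx;
    const double k = a / M;
    for (int n = 0; n < N; ++n) {
      const double* __restrict__ xc = xp + ((size_t)n * C + c) * plane;
      const double* __restrict__ gc = gp + ((size_t)n * C + c) * plane;
      double* __restrict__ gxc = gxp + ((size_t)n * C + c) * plane;
      for (size_t t = 0; t < plane; ++t) {
        const double act = a * xc[t] + b0;
        const double g = act > 0 ? gc[t] : 0.0;
        const double xhat = (xc[t] - mu) * istd;
        gxc[t] = k * (M * g - sg - xhat * sgx);
      }
    }
  }
  return List::create(Named("gx") = gx, Named("ggamma") = ggamma,
                      Named("gbeta") = gbeta);
}
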