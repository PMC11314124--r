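// Low-level dense tensor kernels for the detector.
//
// Tensors are numeric 4-D R arrays with dim (H, W, C, N), column-major, so a
// (H*W, C) slab per image is contiguous.  Convolutions are im2col + GEMM in
// single precision (the field's customary compute precision) via Armadillo;
// elementwise batch-norm / activation / gating kernels are fused single-pass
// double-precision loops.  Convolution weights are stored as a (Cin*k*k) x
// Cout matrix whose row index is ci*k*k + i*k + j for kernel tap (i, j) of
// input channel ci.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p, int d) {
  return (n + 2 * p - d * (k - 1) - 1) / s + 1;
}

// Fill colT (Q x K) for one image; Q = Ho*Wo ordered h-fastest, K = Cin*k*k.
static void im2col_t(const double* x, int H, int W, int C,
                     int k, int s, int p, int d,
                     int Ho, int Wo, arma::fmat& colT) {
  if (k == 1 && s == 1 && p == 0) {            // 1x1 conv: plain cast
    float* dst = colT.memptr();
    const size_t n = (size_t)H * W * C;
    for (size_t i = 0; i < n; ++i) dst[i] = (float)x[i];
    return;
  }
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)ci * H * W;
    for (int i = 0; i < k; ++i) {
      for (int j = 0; j < k; ++j) {
        const int r = ci * k * k + i * k + j;
        float* dst = colT.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + j * d;
          float* dcol = dst + (size_t)wo * Ho;
          if (wi < 0 || wi >= W) {
            std::fill(dcol, dcol + Ho, 0.0f);
            continue;
          }
          const double* xcw = xc + (size_t)wi * H;
          if (s == 1) {
            const int h0 = std::max(0, p - i * d);
            const int h1 = std::min(Ho, H + p - i * d);
            for (int ho = 0; ho < h0; ++ho) dcol[ho] = 0.0f;
            const double* src = xcw - p + i * d;
            for (int ho = h0; ho < h1; ++ho) dcol[ho] = (float)src[ho];
            for (int ho = h1; ho < Ho; ++ho) dcol[ho] = 0.0f;
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * s - p + i * d;
              dcol[ho] = (hi >= 0 && hi < H) ? (float)xcw[hi] : 0.0f;
            }
          }
        }
      }
    }
  }
}

// Scatter-add dcolT (Q x K) into dx for one image.
static void col2im_t(const arma::fmat& dcolT, int H, int W, int C,
                     int k, int s, int p, int d,
                     int Ho, int Wo, double* dx) {
  if (k == 1 && s == 1 && p == 0) {
    const float* src = dcolT.memptr();
    const size_t n = (size_t)H * W * C;
    for (size_t i = 0; i < n; ++i) dx[i] += (double)src[i];
    return;
  }
  for (int ci = 0; ci < C; ++ci) {
    double* xc = dx + (size_t)ci * H * W;
    for (int i = 0; i < k; ++i) {
      for (int j = 0; j < k; ++j) {
        const int r = ci * k * k + i * k + j;
        const float* src = dcolT.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + j * d;
          if (wi < 0 || wi >= W) continue;
          double* xcw = xc + (size_t)wi * H;
          const float* scol = src + (size_t)wo * Ho;
          if (s == 1) {
            const int h0 = std::max(0, p - i * d);
            const int h1 = std::min(Ho, H + p - i * d);
            double* dst = xcw - p + i * d;
            for (int ho = h0; ho < h1; ++ho) dst[ho] += (double)scol[ho];
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * s - p + i * d;
              if (hi >= 0 && hi < H) xcw[hi] += (double)scol[ho];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericMatrix wmat,
                            NumericVector bias,
                            int k, int stride, int pad, int dil) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int K = C * k * k, Co = wmat.ncol();
  if (wmat.nrow() != K) stop("conv weight rows %d != Cin*k*k (%d)", wmat.nrow(), K);
  const int Ho = out_size(H, k, stride, pad, dil);
  const int Wo = out_size(W, k, stride, pad, dil);
  if (Ho <= 0 || Wo <= 0) stop("conv output would be empty");
  const int Q = Ho * Wo;
  NumericVector out(no_init((size_t)Q * Co * N));
  out.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  arma::fmat Wf(K, Co);
  { const double* pw = wmat.begin(); float* pf = Wf.memptr();
    for (size_t i = 0; i < (size_t)K * Co; ++i) pf[i] = (float)pw[i]; }
  arma::fmat colT(Q, K), O(Q, Co);
  const bool has_b = bias.size() == Co;
  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, dil, Ho, Wo, colT);
    O = colT * Wf;
    double* po = out.begin() + (size_t)n * Q * Co;
    const float* pf = O.memptr();
    if (has_b) {
      for (int co = 0; co < Co; ++co) {
        const double bc = bias[co];
        const float* col = pf + (size_t)co * Q;
        double* dst = po + (size_t)co * Q;
        for (int q = 0; q < Q; ++q) dst[q] = (double)col[q] + bc;
      }
    } else {
      for (size_t i = 0; i < (size_t)Q * Co; ++i) po[i] = (double)pf[i];
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericMatrix wmat, NumericVector dout,
                   int k, int stride, int pad, int dil,
                   bool need_dx, bool need_db) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  IntegerVector dmo = dout.attr("dim");
  const int Ho = dmo[0], Wo = dmo[1], Co = dmo[2];
  const int K = C * k * k, Q = Ho * Wo;
  arma::fmat Wf(K, Co);
  { const double* pw = wmat.begin(); float* pf = Wf.memptr();
    for (size_t i = 0; i < (size_t)K * Co; ++i) pf[i] = (float)pw[i]; }
  arma::fmat dW(K, Co, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)H * W * C * N);   // zero-filled: col2im adds
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  NumericVector db(need_db ? Co : 0);
  arma::fmat colT(Q, K), dOf(Q, Co), dcolT;
  for (int n = 0; n < N; ++n) {
    const double* pd = dout.begin() + (size_t)n * Q * Co;
    { float* pf = dOf.memptr();
      for (size_t i = 0; i < (size_t)Q * Co; ++i) pf[i] = (float)pd[i]; }
    im2col_t(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, dil, Ho, Wo, colT);
    dW += colT.t() * dOf;
    if (need_db)
      for (int co = 0; co < Co; ++co) {
        double s = 0;
        const double* col = pd + (size_t)co * Q;
        for (int q = 0; q < Q; ++q) s += col[q];
        db[co] += s;
      }
    if (need_dx) {
      dcolT = dOf * Wf.t();
      col2im_t(dcolT, H, W, C, k, stride, pad, dil, Ho, Wo,
               dx.begin() + (size_t)n * H * W * C);
    }
  }
  NumericMatrix dWr(K, Co);
  { const float* pf = dW.memptr(); double* pd = dWr.begin();
    for (size_t i = 0; i < (size_t)K * Co; ++i) pd[i] = (double)pf[i]; }
  return List::create(_["dx"] = dx, _["dw"] = dWr, _["db"] = db);
}

// ---- batch norm + SiLU, fused ---------------------------------------------

// per-channel mean and population variance over (H, W, N)
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const size_t hw = (size_t)H * W;
  NumericVector mu(C), va(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((size_t)n * C + c) * hw;
      double s = 0, s2 = 0;
      for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      mu[c] += s; va[c] += s2;
    }
  const double M = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    mu[c] /= M;
    va[c] = std::max(va[c] / M - mu[c] * mu[c], 0.0);
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}

static inline double silu_grad(double pre, double s) {
  return s * (1.0 + pre * (1.0 - s));
}

// y = silu(g * (x - mu) * istd + b)
// [[Rcpp::export]]
NumericVector cpp_bn_silu_fw(NumericVector x, NumericVector g, NumericVector b,
                             NumericVector mu, NumericVector istd) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const size_t hw = (size_t)H * W;
  NumericVector y(no_init(x.size()));
  y.attr("dim") = dm;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double a = g[c] * istd[c];
      const double bb = b[c] - g[c] * mu[c] * istd[c];
      const double* px = x.begin() + ((size_t)n * C + c) * hw;
      double* py = y.begin() + ((size_t)n * C + c) * hw;
      for (size_t i = 0; i < hw; ++i) {
        const double pre = a * px[i] + bb;
        py[i] = pre / (1.0 + std::exp(-pre));
      }
    }
  return y;
}

// backward of BN+SiLU; recomputes pre-activations from x.
// training=TRUE uses batch-stat backward, else running-stat (affine) backward.
// [[Rcpp::export]]
List cpp_bn_silu_bw(NumericVector dout, NumericVector x,
                    NumericVector g, NumericVector b,
                    NumericVector mu, NumericVector istd, bool training) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const size_t hw = (size_t)H * W;
  const double M = (double)hw * N;
  NumericVector dx(no_init(x.size()));
  dx.attr("dim") = dm;
  NumericVector dg(C), db(C), s1(C), s2(C);
  // pass 1: dpre and channel sums; stash dpre in dx
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double a = g[c] * istd[c];
      const double bb = b[c] - g[c] * mu[c] * istd[c];
      const size_t off = ((size_t)n * C + c) * hw;
      const double* px = x.begin() + off;
      const double* pd = dout.begin() + off;
      double* pz = dx.begin() + off;
      double sg = 0, sb = 0, t1 = 0, t2 = 0;
      for (size_t i = 0; i < hw; ++i) {
        const double xh = (px[i] - mu[c]) * istd[c];
        const double pre = a * px[i] + bb;
        const double sig = 1.0 / (1.0 + std::exp(-pre));
        const double dpre = pd[i] * silu_grad(pre, sig);
        sg += dpre * xh; sb += dpre;
        t1 += dpre; t2 += dpre * xh;
        pz[i] = dpre;
      }
      dg[c] += sg; db[c] += sb; s1[c] += t1; s2[c] += t2;
    }
  // pass 2: dx
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double* px = x.begin() + off;
      double* pz = dx.begin() + off;
      const double gi = g[c] * istd[c];
      if (training) {
        const double m1 = s1[c] / M, m2 = s2[c] / M;
        for (size_t i = 0; i < hw; ++i) {
          const double xh = (px[i] - mu[c]) * istd[c];
          pz[i] = gi * (pz[i] - m1 - xh * m2);
        }
      } else {
        for (size_t i = 0; i < hw; ++i) pz[i] *= gi;
      }
    }
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}

// plain SiLU
// [[Rcpp::export]]
NumericVector cpp_silu_fw(NumericVector x) {
  NumericVector y(no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  const double* px = x.begin(); double* py = y.begin();
  const size_t n = x.size();
  for (size_t i = 0; i < n; ++i) py[i] = px[i] / (1.0 + std::exp(-px[i]));
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_silu_bw(NumericVector dout, NumericVector x) {
  NumericVector dx(no_init(x.size()));
  dx.attr("dim") = x.attr("dim");
  const double* px = x.begin(); const double* pd = dout.begin();
  double* pz = dx.begin();
  const size_t n = x.size();
  for (size_t i = 0; i < n; ++i) {
    const double s = 1.0 / (1.0 + std::exp(-px[i]));
    pz[i] = pd[i] * silu_grad(px[i], s);
  }
  return dx;
}

// ---- SAC switch mixing -----------------------------------------------------

// y = s * b1 + (1 - s) * b2, s has one channel
// [[Rcpp::export]]
NumericVector cpp_sac_mix_fw(NumericVector b1, NumericVector b2, NumericVector s) {
  IntegerVector dm = b1.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const size_t hw = (size_t)H * W;
  NumericVector y(no_init(b1.size()));
  y.attr("dim") = dm;
  for (int n = 0; n < N; ++n) {
    const double* ps = s.begin() + (size_t)n * hw;
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double* p1 = b1.begin() + off;
      const double* p2 = b2.begin() + off;
      double* py = y.begin() + off;
      for (size_t i = 0; i < hw; ++i)
        py[i] = ps[i] * p1[i] + (1.0 - ps[i]) * p2[i];
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_sac_mix_bw(NumericVector dout, NumericVector b1, NumericVector b2,
                    NumericVector s) {
  IntegerVector dm = b1.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const size_t hw = (size_t)H * W;
  NumericVector d1(no_init(b1.size())), d2(no_init(b1.size()));
  d1.attr("dim") = dm; d2.attr("dim") = dm;
  NumericVector ds((size_t)hw * N);
  ds.attr("dim") = IntegerVector::create(H, W, 1, N);
  for (int n = 0; n < N; ++n) {
    double* pds = ds.begin() + (size_t)n * hw;
    const double* ps = s.begin() + (size_t)n * hw;
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double* pd = dout.begin() + off;
      const double* p1 = b1.begin() + off;
      const double* p2 = b2.begin() + off;
      double* q1 = d1.begin() + off;
      double* q2 = d2.begin() + off;
      for (size_t i = 0; i < hw; ++i) {
        q1[i] = pd[i] * ps[i];
        q2[i] = pd[i] * (1.0 - ps[i]);
        pds[i] += pd[i] * (p1[i] - p2[i]);
      }
    }
  }
  return List::create(_["db1"] = d1, _["db2"] = d2, _["ds"] = ds);
}

// ---- channel broadcasts ----------------------------------------------------

// y = x * m[c, n]
// [[Rcpp::export]]
NumericVector cpp_mul_cn(NumericVector x, NumericMatrix m) {
  IntegerVector dm = x.attr("dim");
  const int C = dm[2], N = dm[3];
  const size_t hw = (size_t)dm[0] * dm[1];
  NumericVector y(no_init(x.size()));
  y.attr("dim") = dm;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double v = m(c, n);
      const size_t off = ((size_t)n * C + c) * hw;
      const double* px = x.begin() + off;
      double* py = y.begin() + off;
      for (size_t i = 0; i < hw; ++i) py[i] = px[i] * v;
    }
  return y;
}

// (C, N) spatial sums of a * b (pass b of length 0 for sums of a alone)
// [[Rcpp::export]]
NumericMatrix cpp_csum_mul(NumericVector a, NumericVector b) {
  IntegerVector dm = a.attr("dim");
  const int C = dm[2], N = dm[3];
  const size_t hw = (size_t)dm[0] * dm[1];
  NumericMatrix out(C, N);
  const bool two = b.size() == a.size();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double* pa = a.begin() + off;
      double s = 0;
      if (two) {
        const double* pb = b.begin() + off;
        for (size_t i = 0; i < hw; ++i) s += pa[i] * pb[i];
      } else {
        for (size_t i = 0; i < hw; ++i) s += pa[i];
      }
      out(c, n) = s;
    }
  return out;
}

// y = x * s (s one channel, broadcast over C)
// [[Rcpp::export]]
NumericVector cpp_mul_bc1(NumericVector x, NumericVector s) {
  IntegerVector dm = x.attr("dim");
  const int C = dm[2], N = dm[3];
  const size_t hw = (size_t)dm[0] * dm[1];
  NumericVector y(no_init(x.size()));
  y.attr("dim") = dm;
  for (int n = 0; n < N; ++n) {
    const double* ps = s.begin() + (size_t)n * hw;
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double* px = x.begin() + off;
      double* py = y.begin() + off;
      for (size_t i = 0; i < hw; ++i) py[i] = px[i] * ps[i];
    }
  }
  return y;
}

// one-channel map of sum over channels of a * b (same shape)
// [[Rcpp::export]]
NumericVector cpp_sum_mul_over_c(NumericVector a, NumericVector b) {
  IntegerVector dm = a.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const size_t hw = (size_t)H * W;
  NumericVector out((size_t)hw * N);
  out.attr("dim") = IntegerVector::create(H, W, 1, N);
  for (int n = 0; n < N; ++n) {
    double* po = out.begin() + (size_t)n * hw;
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double* pa = a.begin() + off;
      const double* pb = b.begin() + off;
      for (size_t i = 0; i < hw; ++i) po[i] += pa[i] * pb[i];
    }
  }
  return out;
}

// add a (C, N) matrix broadcast over space: y = x + m[c, n]
// [[Rcpp::export]]
NumericVector cpp_add_cn(NumericVector x, NumericMatrix m) {
  IntegerVector dm = x.attr("dim");
  const int C = dm[2], N = dm[3];
  const size_t hw = (size_t)dm[0] * dm[1];
  NumericVector y(no_init(x.size()));
  y.attr("dim") = dm;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double v = m(c, n);
      const size_t off = ((size_t)n * C + c) * hw;
      const double* px = x.begin() + off;
      double* py = y.begin() + off;
      for (size_t i = 0; i < hw; ++i) py[i] = px[i] + v;
    }
  return y;
}

// channel mean and max maps (2-channel stack) + argmax channel per pixel
// [[Rcpp::export]]
List cpp_channel_meanmax(NumericVector x) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const size_t hw = (size_t)H * W;
  NumericVector cat((size_t)hw * 2 * N);
  cat.attr("dim") = IntegerVector::create(H, W, 2, N);
  IntegerVector am((size_t)hw * N);
  for (int n = 0; n < N; ++n) {
    double* pmu = cat.begin() + (size_t)n * 2 * hw;
    double* pmx = pmu + hw;
    int* pam = am.begin() + (size_t)n * hw;
    const double* p0 = x.begin() + (size_t)n * C * hw;
    for (size_t i = 0; i < hw; ++i) { pmu[i] = p0[i]; pmx[i] = p0[i]; pam[i] = 0; }
    for (int c = 1; c < C; ++c) {
      const double* pc = x.begin() + ((size_t)n * C + c) * hw;
      for (size_t i = 0; i < hw; ++i) {
        pmu[i] += pc[i];
        if (pc[i] > pmx[i]) { pmx[i] = pc[i]; pam[i] = c; }
      }
    }
    const double invC = 1.0 / C;
    for (size_t i = 0; i < hw; ++i) pmu[i] *= invC;
  }
  return List::create(_["cat"] = cat, _["argmax"] = am);
}

// backward of the mean/max stack
// [[Rcpp::export]]
NumericVector cpp_channel_meanmax_bw(NumericVector dcat, IntegerVector am,
                                     IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t hw = (size_t)H * W;
  NumericVector dx((size_t)hw * C * N);
  dx.attr("dim") = xdim;
  const double invC = 1.0 / C;
  for (int n = 0; n < N; ++n) {
    const double* dmu = dcat.begin() + (size_t)n * 2 * hw;
    const double* dmx = dmu + hw;
    const int* pam = am.begin() + (size_t)n * hw;
    double* px = dx.begin() + (size_t)n * C * hw;
    for (int c = 0; c < C; ++c) {
      double* pc = px + (size_t)c * hw;
      for (size_t i = 0; i < hw; ++i) pc[i] = dmu[i] * invC;
    }
    for (size_t i = 0; i < hw; ++i) px[(size_t)pam[i] * hw + i] += dmx[i];
  }
  return dx;
}

// ---- concat / split over channels -----------------------------------------

// [[Rcpp::export]]
NumericVector cpp_concat_c(List xs) {
  const int m = xs.size();
  std::vector<NumericVector> v(m);
  int Ctot = 0, H = 0, W = 0, N = 0;
  for (int i = 0; i < m; ++i) {
    v[i] = as<NumericVector>(xs[i]);
    IntegerVector dm = v[i].attr("dim");
    if (i == 0) { H = dm[0]; W = dm[1]; N = dm[3]; }
    Ctot += dm[2];
  }
  const size_t hw = (size_t)H * W;
  NumericVector out(no_init(hw * Ctot * N));
  out.attr("dim") = IntegerVector::create(H, W, Ctot, N);
  for (int n = 0; n < N; ++n) {
    double* po = out.begin() + (size_t)n * Ctot * hw;
    for (int i = 0; i < m; ++i) {
      IntegerVector dm = v[i].attr("dim");
      const int Ci = dm[2];
      const double* pi = v[i].begin() + (size_t)n * Ci * hw;
      std::copy(pi, pi + (size_t)Ci * hw, po);
      po += (size_t)Ci * hw;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_split_c(NumericVector x, IntegerVector sizes) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], N = dm[3];
  const size_t hw = (size_t)H * W;
  const int m = sizes.size();
  int Ctot = 0;
  for (int i = 0; i < m; ++i) Ctot += sizes[i];
  List out(m);
  int at = 0;
  for (int i = 0; i < m; ++i) {
    const int Ci = sizes[i];
    NumericVector yi(no_init(hw * Ci * N));
    yi.attr("dim") = IntegerVector::create(H, W, Ci, N);
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + ((size_t)n * Ctot + at) * hw;
      double* py = yi.begin() + (size_t)n * Ci * hw;
      std::copy(px, px + (size_t)Ci * hw, py);
    }
    out[i] = yi;
    at += Ci;
  }
  return out;
}

// ---- pooling / upsampling --------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int Ho = out_size(H, k, stride, pad, 1), Wo = out_size(W, k, stride, pad, 1);
  NumericVector out(no_init((size_t)Ho * Wo * C * N));
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(out.size());
  const double* px = x.begin();
  double* po = out.begin();
  int* pi = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -HUGE_VAL; size_t bi = 0;
          for (int j = 0; j < k; ++j) {
            const int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              const double v = px[base + (size_t)wi * H + hi];
              if (v > best) { best = v; bi = base + (size_t)wi * H + hi; }
            }
          }
          const size_t oq = (((size_t)n * C + c) * Wo + wo) * Ho + ho;
          po[oq] = best;
          pi[oq] = (int)bi;
        }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector dout, IntegerVector idx, IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  const double* pd = dout.begin();
  const int* pi = idx.begin();
  double* px = dx.begin();
  const size_t M = dout.size();
  for (size_t q = 0; q < M; ++q) px[pi[q]] += pd[q];
  return dx;
}

// average pooling, zeros included in the divisor (k*k)
// [[Rcpp::export]]
NumericVector cpp_avgpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int Ho = out_size(H, k, stride, pad, 1), Wo = out_size(W, k, stride, pad, 1);
  NumericVector out(no_init((size_t)Ho * Wo * C * N));
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double inv = 1.0 / (k * k);
  const double* px = x.begin();
  double* po = out.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double s = 0.0;
          for (int j = 0; j < k; ++j) {
            const int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int hi = ho * stride - pad + i;
              if (hi >= 0 && hi < H) s += px[base + (size_t)wi * H + hi];
            }
          }
          po[(((size_t)n * C + c) * Wo + wo) * Ho + ho] = s * inv;
        }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bw(NumericVector dout, IntegerVector xdim,
                             int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector dmo = dout.attr("dim");
  const int Ho = dmo[0], Wo = dmo[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  const double inv = 1.0 / (k * k);
  const double* pd = dout.begin();
  double* px = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = pd[(((size_t)n * C + c) * Wo + wo) * Ho + ho] * inv;
          for (int j = 0; j < k; ++j) {
            const int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int hi = ho * stride - pad + i;
              if (hi >= 0 && hi < H) px[base + (size_t)wi * H + hi] += g;
            }
          }
        }
    }
  return dx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export]]
NumericVector cpp_upsample2_fw(NumericVector x) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  NumericVector out(no_init((size_t)4 * H * W * C * N));
  out.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  const double* px = x.begin();
  double* po = out.begin();
  const size_t S = (size_t)C * N;
  for (size_t s = 0; s < S; ++s) {
    const double* xs = px + s * (size_t)H * W;
    double* os = po + s * (size_t)4 * H * W;
    for (int w = 0; w < W; ++w) {
      const double* xc = xs + (size_t)w * H;
      double* o1 = os + (size_t)(2 * w) * 2 * H;
      double* o2 = os + (size_t)(2 * w + 1) * 2 * H;
      for (int h = 0; h < H; ++h) {
        const double v = xc[h];
        o1[2 * h] = v; o1[2 * h + 1] = v;
        o2[2 * h] = v; o2[2 * h + 1] = v;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(NumericVector dout) {
  IntegerVector dm = dout.attr("dim");
  const int H2 = dm[0], W2 = dm[1], C = dm[2], N = dm[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector dx(no_init((size_t)H * W * C * N));
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* pd = dout.begin();
  double* px = dx.begin();
  const size_t S = (size_t)C * N;
  for (size_t s = 0; s < S; ++s) {
    const double* ds = pd + s * (size_t)H2 * W2;
    double* xs = px + s * (size_t)H * W;
    for (int w = 0; w < W; ++w) {
      const double* d1 = ds + (size_t)(2 * w) * H2;
      const double* d2 = ds + (size_t)(2 * w + 1) * H2;
      double* xc = xs + (size_t)w * H;
      for (int h = 0; h < H; ++h)
        xc[h] = d1[2 * h] + d1[2 * h + 1] + d2[2 * h] + d2[2 * h + 1];
    }
  }
  return dx;
}

// ---- fused conv + batch-norm + SiLU block ----------------------------------
//
// The hot path of the network.  Forward caches the im2col matrices and the
// pre-normalisation conv outputs in single precision behind external
// pointers, so backward needs no refill and no double materialisation of
// intermediates.

struct ConvBlockCache {
  std::vector<float> colT;  // N * (Q*K), h-fastest per image
  std::vector<float> z;     // N * (Q*Co) conv outputs (pre-BN)
  std::vector<float> dbuf;  // backward scratch (dpre -> dz)
  int H, W, C, N, Ho, Wo, K, Co;
};

// [[Rcpp::export]]
List cpp_convblock_fw(NumericVector x, NumericMatrix wmat,
                      NumericVector g, NumericVector b,
                      NumericVector rm, NumericVector rv,
                      int k, int stride, int pad, int dil,
                      bool training, double momentum, double eps,
                      SEXP prev_cache) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int K = C * k * k, Co = wmat.ncol();
  if (wmat.nrow() != K) stop("conv weight rows %d != Cin*k*k (%d)", wmat.nrow(), K);
  const int Ho = out_size(H, k, stride, pad, dil);
  const int Wo = out_size(W, k, stride, pad, dil);
  if (Ho <= 0 || Wo <= 0) stop("conv output would be empty");
  const int Q = Ho * Wo;

  // reuse the previous iteration's buffers when shapes match (std::vector
  // resize keeps capacity, so steady-state training does no reallocation)
  XPtr<ConvBlockCache> cache = Rf_isNull(prev_cache)
    ? XPtr<ConvBlockCache>(new ConvBlockCache(), true)
    : XPtr<ConvBlockCache>(prev_cache);
  cache->H = H; cache->W = W; cache->C = C; cache->N = N;
  cache->Ho = Ho; cache->Wo = Wo; cache->K = K; cache->Co = Co;
  cache->colT.resize((size_t)N * Q * K);
  cache->z.resize((size_t)N * Q * Co);

  arma::fmat Wf(K, Co);
  { const double* pw = wmat.begin(); float* pf = Wf.memptr();
    for (size_t i = 0; i < (size_t)K * Co; ++i) pf[i] = (float)pw[i]; }

  for (int n = 0; n < N; ++n) {
    arma::fmat colT(cache->colT.data() + (size_t)n * Q * K, Q, K, false, true);
    im2col_t(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, dil,
             Ho, Wo, colT);
    arma::fmat Z(cache->z.data() + (size_t)n * Q * Co, Q, Co, false, true);
    Z = colT * Wf;
  }

  // channel statistics over the float conv outputs
  NumericVector mu(Co), va(Co);
  if (training) {
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Co; ++c) {
        const float* pz = cache->z.data() + ((size_t)n * Co + c) * Q;
        double s = 0, s2 = 0;
        for (int q = 0; q < Q; ++q) { s += pz[q]; s2 += (double)pz[q] * pz[q]; }
        mu[c] += s; va[c] += s2;
      }
    const double M = (double)Q * N;
    for (int c = 0; c < Co; ++c) {
      mu[c] /= M;
      va[c] = std::max(va[c] / M - mu[c] * mu[c], 0.0);
    }
  } else {
    for (int c = 0; c < Co; ++c) { mu[c] = rm[c]; va[c] = rv[c]; }
  }
  NumericVector istd(Co);
  for (int c = 0; c < Co; ++c) istd[c] = 1.0 / std::sqrt(va[c] + eps);

  NumericVector rm_new(Co), rv_new(Co);
  if (training) {
    const double M = (double)Q * N;
    const double unbias = M / std::max(M - 1.0, 1.0);
    for (int c = 0; c < Co; ++c) {
      rm_new[c] = (1 - momentum) * rm[c] + momentum * mu[c];
      rv_new[c] = (1 - momentum) * rv[c] + momentum * va[c] * unbias;
    }
  } else { rm_new = rm; rv_new = rv; }

  NumericVector y(no_init((size_t)Q * Co * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Co; ++c) {
      const float a = (float)(g[c] * istd[c]);
      const float bb = (float)(b[c] - g[c] * mu[c] * istd[c]);
      const float* pz = cache->z.data() + ((size_t)n * Co + c) * Q;
      double* py = y.begin() + ((size_t)n * Co + c) * Q;
      for (int q = 0; q < Q; ++q) {
        const float pre = a * pz[q] + bb;
        py[q] = (double)(pre / (1.0f + std::exp(-pre)));
      }
    }
  return List::create(_["y"] = y, _["cache"] = cache, _["mu"] = mu,
                      _["istd"] = istd, _["rm"] = rm_new, _["rv"] = rv_new);
}

// [[Rcpp::export]]
List cpp_convblock_bw(NumericVector dout, SEXP cache_sexp, NumericMatrix wmat,
                      NumericVector g, NumericVector b,
                      NumericVector mu, NumericVector istd,
                      int k, int stride, int pad, int dil,
                      bool training, bool need_dx) {
  XPtr<ConvBlockCache> cache(cache_sexp);
  const int H = cache->H, W = cache->W, C = cache->C, N = cache->N;
  const int Ho = cache->Ho, Wo = cache->Wo, K = cache->K, Co = cache->Co;
  const int Q = Ho * Wo;
  const double M = (double)Q * N;

  // pass 1: dpre (persistent scratch), channel sums
  cache->dbuf.resize((size_t)N * Q * Co);
  std::vector<float>& dpre = cache->dbuf;
  NumericVector dg(Co), db(Co), s1(Co), s2(Co);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Co; ++c) {
      const float a = (float)(g[c] * istd[c]);
      const float bb = (float)(b[c] - g[c] * mu[c] * istd[c]);
      const float muc = (float)mu[c], ic = (float)istd[c];
      const size_t off = ((size_t)n * Co + c) * Q;
      const float* pz = cache->z.data() + off;
      const double* pd = dout.begin() + off;
      float* pp = dpre.data() + off;
      double sg = 0, sb = 0;
      for (int q = 0; q < Q; ++q) {
        const float pre = a * pz[q] + bb;
        const float sig = 1.0f / (1.0f + std::exp(-pre));
        const float dp = (float)pd[q] * (sig * (1.0f + pre * (1.0f - sig)));
        const float xh = (pz[q] - muc) * ic;
        sg += (double)dp * xh;
        sb += dp;
        pp[q] = dp;
      }
      dg[c] += sg; db[c] += sb; s1[c] += sb; s2[c] += sg;
    }

  // pass 2: dz in float (overwrite dpre buffer)
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Co; ++c) {
      const float gi = (float)(g[c] * istd[c]);
      const size_t off = ((size_t)n * Co + c) * Q;
      float* pp = dpre.data() + off;
      if (training) {
        const float m1 = (float)(s1[c] / M), m2 = (float)(s2[c] / M);
        const float muc = (float)mu[c], ic = (float)istd[c];
        const float* pz = cache->z.data() + off;
        for (int q = 0; q < Q; ++q) {
          const float xh = (pz[q] - muc) * ic;
          pp[q] = gi * (pp[q] - m1 - xh * m2);
        }
      } else {
        for (int q = 0; q < Q; ++q) pp[q] *= gi;
      }
    }

  // conv backward from cached colT
  arma::fmat Wf(K, Co);
  { const double* pw = wmat.begin(); float* pf = Wf.memptr();
    for (size_t i = 0; i < (size_t)K * Co; ++i) pf[i] = (float)pw[i]; }
  arma::fmat dW(K, Co, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)H * W * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  arma::fmat dcolT;
  for (int n = 0; n < N; ++n) {
    arma::fmat colT(cache->colT.data() + (size_t)n * Q * K, Q, K, false, true);
    arma::fmat dZ(dpre.data() + (size_t)n * Q * Co, Q, Co, false, true);
    dW += colT.t() * dZ;
    if (need_dx) {
      dcolT = dZ * Wf.t();
      col2im_t(dcolT, H, W, C, k, stride, pad, dil, Ho, Wo,
               dx.begin() + (size_t)n * H * W * C);
    }
  }
  NumericMatrix dWr(K, Co);
  { const float* pf = dW.memptr(); double* pd = dWr.begin();
    for (size_t i = 0; i < (size_t)K * Co; ++i) pd[i] = (double)pf[i]; }
  return List::create(_["dx"] = dx, _["dw"] = dWr, _["dg"] = dg, _["db"] = db);
}

// ---- fused dual-branch SAC convolution -------------------------------------
//
// The two stride-1 branches (dilation 1 and dilation r) share the input;
// forward caches both im2col matrices in single precision so backward does
// two GEMM pairs and a shared col2im accumulation with no refill.

struct SacConvCache {
  std::vector<float> col1, col2;
  int H, W, C, N, Q, K;
};

// [[Rcpp::export]]
List cpp_sacconv_fw(NumericVector x, NumericMatrix wmat, NumericMatrix dwmat,
                    int k, int r, SEXP prev_cache) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int K = C * k * k, Co = wmat.ncol();
  const int p1 = (k - 1) / 2, p2 = r * (k - 1) / 2;
  const int Q = H * W;   // stride 1, same padding
  XPtr<SacConvCache> cache = Rf_isNull(prev_cache)
    ? XPtr<SacConvCache>(new SacConvCache(), true)
    : XPtr<SacConvCache>(prev_cache);
  cache->H = H; cache->W = W; cache->C = C; cache->N = N;
  cache->Q = Q; cache->K = K;
  cache->col1.resize((size_t)N * Q * K);
  cache->col2.resize((size_t)N * Q * K);
  arma::fmat W1(K, Co), W2(K, Co);
  { const double* pw = wmat.begin(); const double* pd = dwmat.begin();
    float* p1f = W1.memptr(); float* p2f = W2.memptr();
    for (size_t i = 0; i < (size_t)K * Co; ++i) {
      p1f[i] = (float)pw[i];
      p2f[i] = (float)(pw[i] + pd[i]);
    } }
  NumericVector b1(no_init((size_t)Q * Co * N)), b2(no_init((size_t)Q * Co * N));
  b1.attr("dim") = IntegerVector::create(H, W, Co, N);
  b2.attr("dim") = IntegerVector::create(H, W, Co, N);
  arma::fmat O(Q, Co);
  for (int n = 0; n < N; ++n) {
    arma::fmat c1(cache->col1.data() + (size_t)n * Q * K, Q, K, false, true);
    arma::fmat c2(cache->col2.data() + (size_t)n * Q * K, Q, K, false, true);
    im2col_t(x.begin() + (size_t)n * Q * C, H, W, C, k, 1, p1, 1, H, W, c1);
    im2col_t(x.begin() + (size_t)n * Q * C, H, W, C, k, 1, p2, r, H, W, c2);
    O = c1 * W1;
    double* po = b1.begin() + (size_t)n * Q * Co;
    const float* pf = O.memptr();
    for (size_t i = 0; i < (size_t)Q * Co; ++i) po[i] = (double)pf[i];
    O = c2 * W2;
    po = b2.begin() + (size_t)n * Q * Co;
    pf = O.memptr();
    for (size_t i = 0; i < (size_t)Q * Co; ++i) po[i] = (double)pf[i];
  }
  return List::create(_["b1"] = b1, _["b2"] = b2, _["cache"] = cache);
}

// [[Rcpp::export]]
List cpp_sacconv_bw(NumericVector db1, NumericVector db2, SEXP cache_sexp,
                    NumericMatrix wmat, NumericMatrix dwmat,
                    int k, int r, bool need_dx) {
  XPtr<SacConvCache> cache(cache_sexp);
  const int H = cache->H, W = cache->W, C = cache->C, N = cache->N;
  const int Q = cache->Q, K = cache->K;
  IntegerVector dmo = db1.attr("dim");
  const int Co = dmo[2];
  const int p1 = (k - 1) / 2, p2 = r * (k - 1) / 2;
  arma::fmat W1(K, Co), W2(K, Co);
  { const double* pw = wmat.begin(); const double* pd = dwmat.begin();
    float* p1f = W1.memptr(); float* p2f = W2.memptr();
    for (size_t i = 0; i < (size_t)K * Co; ++i) {
      p1f[i] = (float)pw[i];
      p2f[i] = (float)(pw[i] + pd[i]);
    } }
  arma::fmat dW1(K, Co, arma::fill::zeros), dW2(K, Co, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)Q * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  arma::fmat dO(Q, Co), dcol;
  for (int n = 0; n < N; ++n) {
    arma::fmat c1(cache->col1.data() + (size_t)n * Q * K, Q, K, false, true);
    arma::fmat c2(cache->col2.data() + (size_t)n * Q * K, Q, K, false, true);
    const double* pd1 = db1.begin() + (size_t)n * Q * Co;
    { float* pf = dO.memptr();
      for (size_t i = 0; i < (size_t)Q * Co; ++i) pf[i] = (float)pd1[i]; }
    dW1 += c1.t() * dO;
    if (need_dx) {
      dcol = dO * W1.t();
      col2im_t(dcol, H, W, C, k, 1, p1, 1, H, W, dx.begin() + (size_t)n * Q * C);
    }
    const double* pd2 = db2.begin() + (size_t)n * Q * Co;
    { float* pf = dO.memptr();
      for (size_t i = 0; i < (size_t)Q * Co; ++i) pf[i] = (float)pd2[i]; }
    dW2 += c2.t() * dO;
    if (need_dx) {
      dcol = dO * W2.t();
      col2im_t(dcol, H, W, C, k, 1, p2, r, H, W, dx.begin() + (size_t)n * Q * C);
    }
  }
  NumericMatrix d1(K, Co), d2(K, Co);
  { const float* pf = dW1.memptr(); double* pd = d1.begin();
    for (size_t i = 0; i < (size_t)K * Co; ++i) pd[i] = (double)pf[i]; }
  { const float* pf = dW2.memptr(); double* pd = d2.begin();
    for (size_t i = 0; i < (size_t)K * Co; ++i) pd[i] = (double)pf[i]; }
  return List::create(_["dw1"] = d1, _["dw2"] = d2, _["dx"] = dx);
}
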