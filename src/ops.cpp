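// Low-level tensor kernels for the detector runtime.
//
// Feature maps are numeric arrays with dim c(H, W, C, N) (column-major, H
// fastest). Convolution weights have dim c(k, k, C_in/groups, C_out).
// Convolution is implemented as im2col + BLAS gemm; the column matrix is laid
// out (Ho*Wo*N) x (k*k*Cg) so that both the gather and the gemm operands are
// contiguous. The backward pass uses the transposed gemms plus a col2im
// scatter-add. Interfaces are double; conv gemms run in single precision internally.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// Single-precision is used internally for the convolution gemms (inputs and
// results are double at the R boundary): halves memory traffic and doubles
// BLAS throughput at a precision amply sufficient for detector training.

// Gather patches of channels [c0, c0+Cg) into colT: (Ho*Wo*N) x (k*k*Cg).
static void im2colT(const double* x, int H, int W, int C, int N,
                    int k, int s, int p, int c0, int Cg, arma::fmat& colT) {
  const int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  const long HW = (long)H * W, HWC = HW * C, HoWo = (long)Ho * Wo;
  for (int c = 0; c < Cg; ++c)
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        float* dst = colT.colptr((long)kh + k * ((long)kw + (long)k * c));
        for (int n = 0; n < N; ++n) {
          const double* xc = x + (long)n * HWC + (long)(c0 + c) * HW;
          float* d = dst + (long)n * HoWo;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * s - p + kw;
            float* drow = d + (long)wo * Ho;
            if (w < 0 || w >= W) {
              for (int ho = 0; ho < Ho; ++ho) drow[ho] = 0.0f;
              continue;
            }
            const double* xcw = xc + (long)w * H;
            if (s == 1) {
              const int h0 = -p + kh;
              int ho = 0;
              for (; ho < Ho && h0 + ho < 0; ++ho) drow[ho] = 0.0f;
              const int hi = std::min(Ho, H - h0);
              for (; ho < hi; ++ho) drow[ho] = (float)xcw[h0 + ho];
              for (; ho < Ho; ++ho) drow[ho] = 0.0f;
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                const int h = ho * s - p + kh;
                drow[ho] = (h < 0 || h >= H) ? 0.0f : (float)xcw[h];
              }
            }
          }
        }
      }
}

// Scatter-add colT gradients back onto input channels [c0, c0+Cg).
static void col2imT(const arma::fmat& colT, int H, int W, int C, int N,
                    int k, int s, int p, int c0, int Cg, double* gx) {
  const int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  const long HW = (long)H * W, HWC = HW * C, HoWo = (long)Ho * Wo;
  for (int c = 0; c < Cg; ++c)
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const float* src = colT.colptr((long)kh + k * ((long)kw + (long)k * c));
        for (int n = 0; n < N; ++n) {
          double* xc = gx + (long)n * HWC + (long)(c0 + c) * HW;
          const float* srow0 = src + (long)n * HoWo;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * s - p + kw;
            if (w < 0 || w >= W) continue;
            double* xcw = xc + (long)w * H;
            const float* srow = srow0 + (long)wo * Ho;
            for (int ho = 0; ho < Ho; ++ho) {
              const int h = ho * s - p + kh;
              if (h >= 0 && h < H) xcw[h] += srow[ho];
            }
          }
        }
      }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, IntegerVector xdim,
                        NumericVector w, IntegerVector wdim,
                        Nullable<NumericVector> bias,
                        int stride, int pad, int groups) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wdim[0], Cg = wdim[2], Co = wdim[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  const int Cog = Co / groups;
  const long cols = (long)Ho * Wo * N, HoWo = (long)Ho * Wo;
  NumericVector y(HoWo * Co * N);
  arma::fmat colT(cols, (long)k * k * Cg);
  arma::fmat Wf((long)k * k * Cg, Co);
  { const double* wp = w.begin(); float* fp = Wf.memptr();
    const long nw = (long)k * k * Cg * Co;
    for (long i = 0; i < nw; ++i) fp[i] = (float)wp[i]; }
  for (int g = 0; g < groups; ++g) {
    im2colT(x.begin(), H, W, C, N, k, stride, pad, g * Cg, Cg, colT);
    arma::fmat out = colT * Wf.cols(g * Cog, (g + 1) * Cog - 1);  // cols x Cog
    // scatter to (Ho,Wo,Co,N): per (n, channel) contiguous chunks
    for (int c = 0; c < Cog; ++c) {
      const float* src = out.colptr(c);
      for (int n = 0; n < N; ++n) {
        double* dst = y.begin() + ((long)n * Co + g * Cog + c) * HoWo;
        const float* sp = src + (long)n * HoWo;
        for (long i = 0; i < HoWo; ++i) dst[i] = (double)sp[i];
      }
    }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (long n = 0; n < N; ++n)
      for (int c = 0; c < Co; ++c) {
        double* yb = y.begin() + ((long)n * Co + c) * HoWo;
        const double bc = b[c];
        for (long i = 0; i < HoWo; ++i) yb[i] += bc;
      }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, IntegerVector xdim,
               NumericVector w, IntegerVector wdim,
               NumericVector gy, bool has_bias,
               int stride, int pad, int groups, bool need_gx) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wdim[0], Cg = wdim[2], Co = wdim[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  const int Cog = Co / groups;
  const long cols = (long)Ho * Wo * N, HoWo = (long)Ho * Wo;

  NumericVector gw((long)k * k * Cg * Co);
  NumericVector gb(has_bias ? Co : 0);
  NumericVector gx(need_gx ? (long)H * W * C * N : 0);
  arma::fmat Wf((long)k * k * Cg, Co);
  { const double* wp = w.begin(); float* fp = Wf.memptr();
    const long nw = (long)k * k * Cg * Co;
    for (long i = 0; i < nw; ++i) fp[i] = (float)wp[i]; }
  arma::fmat colT(cols, (long)k * k * Cg);
  arma::fmat gyT(cols, Cog);

  for (int g = 0; g < groups; ++g) {
    // gather gy channels of this group into (cols x Cog)
    for (int c = 0; c < Cog; ++c) {
      float* dst = gyT.colptr(c);
      for (int n = 0; n < N; ++n) {
        const double* sp = gy.begin() + ((long)n * Co + g * Cog + c) * HoWo;
        float* dp = dst + (long)n * HoWo;
        for (long i = 0; i < HoWo; ++i) dp[i] = (float)sp[i];
      }
    }
    im2colT(x.begin(), H, W, C, N, k, stride, pad, g * Cg, Cg, colT);
    arma::fmat gWf = colT.t() * gyT;
    { double* gp = gw.begin() + (long)g * Cog * k * k * Cg;
      const float* fp = gWf.memptr();
      const long nb = (long)k * k * Cg * Cog;
      for (long i = 0; i < nb; ++i) gp[i] = (double)fp[i]; }
    if (need_gx) {
      arma::fmat gcolT = gyT * Wf.cols(g * Cog, (g + 1) * Cog - 1).t();
      col2imT(gcolT, H, W, C, N, k, stride, pad, g * Cg, Cg, gx.begin());
    }
    if (has_bias) {
      arma::frowvec s = arma::sum(gyT, 0);
      for (int c = 0; c < Cog; ++c) gb[g * Cog + c] = (double)s(c);
    }
  }
  List res;
  res["gw"] = gw;
  if (has_bias) res["gb"] = gb;
  if (need_gx) {
    gx.attr("dim") = xdim;
    res["gx"] = gx;
  }
  return res;
}

// y = x * a[c] + b[c] per channel (a, b length C); used by batch norm.
// [[Rcpp::export(name = ".scale_shift")]]
NumericVector scale_shift(NumericVector x, IntegerVector xdim,
                          NumericVector a, NumericVector b) {
  const int C = xdim[2], N = xdim[3];
  const long HW = (long)xdim[0] * xdim[1];
  NumericVector y(x.size());
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c];
      const double* xp = x.begin() + ((long)n * C + c) * HW;
      double* yp = y.begin() + ((long)n * C + c) * HW;
      for (long i = 0; i < HW; ++i) yp[i] = xp[i] * ac + bc;
    }
  y.attr("dim") = xdim;
  return y;
}

// per-channel sums over (H, W, N)
// [[Rcpp::export(name = ".channel_sums")]]
NumericVector channel_sums_cpp(NumericVector x, IntegerVector xdim) {
  const int C = xdim[2], N = xdim[3];
  const long HW = (long)xdim[0] * xdim[1];
  NumericVector s(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + ((long)n * C + c) * HW;
      double acc = 0;
      for (long i = 0; i < HW; ++i) acc += xp[i];
      s[c] += acc;
    }
  return s;
}

// [[Rcpp::export(name = ".silu_fw")]]
NumericVector silu_fw(NumericVector x) {
  NumericVector y(x.size());
  for (long i = 0; i < x.size(); ++i) {
    const double s = 1.0 / (1.0 + std::exp(-x[i]));
    y[i] = x[i] * s;
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export(name = ".silu_bw")]]
NumericVector silu_bw(NumericVector x, NumericVector gy) {
  NumericVector g(x.size());
  for (long i = 0; i < x.size(); ++i) {
    const double s = 1.0 / (1.0 + std::exp(-x[i]));
    g[i] = gy[i] * s * (1.0 + x[i] * (1.0 - s));
  }
  g.attr("dim") = x.attr("dim");
  return g;
}

// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(NumericVector x, IntegerVector xdim, int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y((long)Ho * Wo * C * N);
  IntegerVector idx((long)Ho * Wo * C * N);
  const long HW = (long)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((long)n * C + c) * HW;
      const long obase = ((long)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * stride - pad, w0 = wo * stride - pad;
          double best = -1e300; long bi = 0;
          for (int kw = 0; kw < k; ++kw) {
            const int w = w0 + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = h0 + kh;
              if (h < 0 || h >= H) continue;
              const double v = xc[h + (long)w * H];
              if (v > best) { best = v; bi = h + (long)w * H; }
            }
          }
          const long oo = obase + (long)ho + (long)Ho * wo;
          y[oo] = best;
          idx[oo] = (int)(((long)n * C + c) * HW + bi);
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericVector maxpool_bw(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  NumericVector gx((long)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (long i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export(name = ".upsample2_fw")]]
NumericVector upsample2_fw(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector y((long)4 * H * W * C * N);
  const long HW = (long)H * W, HW4 = 4 * HW;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* xc = x.begin() + cn * HW;
    double* yc = y.begin() + cn * HW4;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double v = xc[h + (long)w * H];
        const long b = 2 * h + (long)(2 * w) * (2 * H);
        yc[b] = v; yc[b + 1] = v;
        yc[b + 2 * H] = v; yc[b + 2 * H + 1] = v;
      }
  }
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  return y;
}

// [[Rcpp::export(name = ".upsample2_bw")]]
NumericVector upsample2_bw(NumericVector gy, IntegerVector ydim) {
  const int H2 = ydim[0], W2 = ydim[1], C = ydim[2], N = ydim[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector gx((long)H * W * C * N);
  const long HW = (long)H * W, HW4 = (long)H2 * W2;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* yc = gy.begin() + cn * HW4;
    double* xc = gx.begin() + cn * HW;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const long b = 2 * h + (long)(2 * w) * H2;
        xc[h + (long)w * H] = yc[b] + yc[b + 1] + yc[b + H2] + yc[b + H2 + 1];
      }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return gx;
}
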