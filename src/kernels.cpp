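// Low-level tensor kernels for the autodiff core.
// All 4-D tensors are R arrays with dim (H, W, C, N), column-major,
// so element (h, w, c, n) sits at h + H*(w + W*(c + C*n)).
// Convolution weights use dim (kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}
static inline IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline void get4(const NumericVector& x, int d[4]) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 4) stop("expected a 4-d tensor");
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

static inline int out_size(int in, int k, int s, int p, int dil) {
  int eff = dil * (k - 1) + 1;
  return (in + 2 * p - eff) / s + 1;
}

// im2col for one sample: fills col (kh*kw*Cin x Ho*Wo)
static void im2col(const double* x, int H, int W, int Cin,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   int dh, int dw, int Ho, int Wo, double* col) {
  const int K = kh * kw * Cin;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int m = ho + Ho * wo;
      double* cp = col + (size_t)m * K;
      for (int c = 0; c < Cin; ++c) {
        const double* xc = x + (size_t)c * H * W;
        for (int j = 0; j < kw; ++j) {
          const int win = wo * sw - pw + j * dw;
          if (win < 0 || win >= W) {
            for (int i = 0; i < kh; ++i) cp[i + kh * (j + kw * c)] = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)win * H;
          for (int i = 0; i < kh; ++i) {
            const int hin = ho * sh - ph + i * dh;
            cp[i + kh * (j + kw * c)] =
              (hin < 0 || hin >= H) ? 0.0 : xcol[hin];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w,
                            Nullable<NumericVector> bias,
                            int sh, int sw, int ph, int pw, int dh, int dw) {
  int dx[4], dw_[4];
  get4(x, dx); get4(w, dw_);
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int kh = dw_[0], kw = dw_[1], Cout = dw_[3];
  if (dw_[2] != Cin) stop("conv2d: input has %d channels but weights expect %d", Cin, dw_[2]);
  const int Ho = out_size(H, kh, sh, ph, dh);
  const int Wo = out_size(W, kw, sw, pw, dw);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  const int K = kh * kw * Cin, M = Ho * Wo;

  NumericVector y = alloc4(Ho, Wo, Cout, N);
  arma::mat Wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(K, (size_t)M * N);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin,
           kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo,
           col.memptr() + (size_t)n * M * K);
  }
  arma::mat Yall = col.t() * Wmat; // (M*N x Cout), sample-blocked rows
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) {
      std::memcpy(y.begin() + (size_t)M * (c + (size_t)Cout * n),
                  Yall.colptr(c) + (size_t)n * M, sizeof(double) * M);
    }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c) {
        double* yp = y.begin() + (size_t)M * (c + (size_t)Cout * n);
        const double bc = b[c];
        for (int m = 0; m < M; ++m) yp[m] += bc;
      }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   bool has_bias, bool need_gx,
                   int sh, int sw, int ph, int pw, int dh, int dw) {
  int dx[4], dw_[4], dg[4];
  get4(x, dx); get4(w, dw_); get4(gy, dg);
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int kh = dw_[0], kw = dw_[1], Cout = dw_[3];
  const int Ho = dg[0], Wo = dg[1];
  const int K = kh * kw * Cin, M = Ho * Wo;

  NumericVector gw = alloc4(kh, kw, Cin, Cout);
  NumericVector gb(Cout);
  arma::mat Wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat GW(gw.begin(), K, Cout, false, true);

  arma::mat col(K, (size_t)M * N);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin,
           kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo,
           col.memptr() + (size_t)n * M * K);
  }
  // gather gy into sample-blocked (M*N x Cout)
  arma::mat GY((size_t)M * N, Cout);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) {
      std::memcpy(GY.colptr(c) + (size_t)n * M,
                  gy.begin() + (size_t)M * (c + (size_t)Cout * n),
                  sizeof(double) * M);
    }
  GW = col * GY;
  NumericVector gx;
  if (need_gx) {
    gx = alloc4(H, W, Cin, N);
    arma::mat colg = GY * Wmat.t(); // (M*N x K): column r contiguous over m
    for (int n = 0; n < N; ++n) {
      double* gxp = gx.begin() + (size_t)n * H * W * Cin;
      for (int c = 0; c < Cin; ++c)
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i) {
            const int r = i + kh * (j + kw * c);
            const double* cp = colg.colptr(r) + (size_t)n * M;
            double* gxc = gxp + (size_t)c * H * W;
            for (int wo = 0; wo < Wo; ++wo) {
              const int win = wo * sw - pw + j * dw;
              if (win < 0 || win >= W) continue;
              double* gcol = gxc + (size_t)win * H;
              const double* cpw = cp + (size_t)wo * Ho;
              if (sh == 1) {
                const int h0 = std::max(0, ph - i * dh);
                const int h1 = std::min(Ho, H + ph - i * dh);
                double* gd = gcol - ph + i * dh;
                for (int ho = h0; ho < h1; ++ho) gd[ho] += cpw[ho];
              } else {
                for (int ho = 0; ho < Ho; ++ho) {
                  const int hin = ho * sh - ph + i * dh;
                  if (hin < 0 || hin >= H) continue;
                  gcol[hin] += cpw[ho];
                }
              }
            }
          }
    }
  }
  if (has_bias) {
    for (int c = 0; c < Cout; ++c) gb[c] = arma::accu(GY.col(c));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// fused in-place AdamW update; val, m, v are modified directly
// [[Rcpp::export]]
void cpp_adamw_step(NumericVector val, NumericVector grad, NumericVector m,
                    NumericVector v, double lr, double b1, double b2,
                    double eps, double wd, double bc1, double bc2) {
  const R_xlen_t n = val.size();
  double* pv = val.begin();
  const double* pg = grad.begin();
  double* pm = m.begin();
  double* pvv = v.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double g = pg[i];
    pm[i] = b1 * pm[i] + (1 - b1) * g;
    pvv[i] = b2 * pvv[i] + (1 - b2) * g * g;
    double step = (pm[i] / bc1) / (std::sqrt(pvv[i] / bc2) + eps);
    if (wd > 0) step += wd * pv[i];
    pv[i] -= lr * step;
  }
}

// 2x2 stride-2 max pooling with stored argmax (linear index into x, 1-based)
// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  int d[4]; get4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial size must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)H * W * (c + (size_t)C * n);
      const double* xp = x.begin() + off;
      double* yp = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      int* ip = idx.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -HUGE_VAL; size_t bidx = 0;
          for (int j = 0; j < 2; ++j)
            for (int i = 0; i < 2; ++i) {
              const size_t k = (2 * ho + i) + (size_t)H * (2 * wo + j);
              if (xp[k] > best) { best = xp[k]; bidx = k; }
            }
          yp[ho + (size_t)Ho * wo] = best;
          ip[ho + (size_t)Ho * wo] = (int)(off + bidx) + 1;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_scatter_add(NumericVector gy, IntegerVector idx, int len,
                              IntegerVector outdim) {
  NumericVector gx(len);
  const int n = gy.size();
  for (int i = 0; i < n; ++i) gx[idx[i] - 1] += gy[i];
  gx.attr("dim") = outdim;
  return gx;
}

struct LinW { int i0, i1; double w0, w1; };

static std::vector<LinW> bilinear_weights(int in, int out) {
  std::vector<LinW> v(out);
  const double scale = (double)in / out;
  for (int o = 0; o < out; ++o) {
    double s = (o + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > in - 1) s = in - 1;
    int i0 = (int)std::floor(s);
    int i1 = std::min(i0 + 1, in - 1);
    double f = s - i0;
    v[o] = {i0, i1, 1.0 - f, f};
  }
  return v;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_fw(NumericVector x, int Ho, int Wo) {
  int d[4]; get4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y = alloc4(Ho, Wo, C, N);
  std::vector<LinW> hw = bilinear_weights(H, Ho), ww = bilinear_weights(W, Wo);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        const LinW& b = ww[wo];
        for (int ho = 0; ho < Ho; ++ho) {
          const LinW& a = hw[ho];
          yp[ho + (size_t)Ho * wo] =
            a.w0 * (b.w0 * xp[a.i0 + (size_t)H * b.i0] + b.w1 * xp[a.i0 + (size_t)H * b.i1]) +
            a.w1 * (b.w0 * xp[a.i1 + (size_t)H * b.i0] + b.w1 * xp[a.i1 + (size_t)H * b.i1]);
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bw(NumericVector gy, int H, int W) {
  int d[4]; get4(gy, d);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector gx = alloc4(H, W, C, N);
  std::vector<LinW> hw = bilinear_weights(H, Ho), ww = bilinear_weights(W, Wo);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* gp = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* gyp = gy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        const LinW& b = ww[wo];
        for (int ho = 0; ho < Ho; ++ho) {
          const LinW& a = hw[ho];
          const double g = gyp[ho + (size_t)Ho * wo];
          gp[a.i0 + (size_t)H * b.i0] += a.w0 * b.w0 * g;
          gp[a.i0 + (size_t)H * b.i1] += a.w0 * b.w1 * g;
          gp[a.i1 + (size_t)H * b.i0] += a.w1 * b.w0 * g;
          gp[a.i1 + (size_t)H * b.i1] += a.w1 * b.w1 * g;
        }
      }
    }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_resize_nearest(NumericVector x, int Ho, int Wo) {
  int d[4]; get4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y = alloc4(Ho, Wo, C, N);
  std::vector<int> hi(Ho), wi(Wo);
  for (int o = 0; o < Ho; ++o)
    hi[o] = std::min(H - 1, (int)std::floor((o + 0.5) * H / Ho));
  for (int o = 0; o < Wo; ++o)
    wi[o] = std::min(W - 1, (int)std::floor((o + 0.5) * W / Wo));
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          yp[ho + (size_t)Ho * wo] = xp[hi[ho] + (size_t)H * wi[wo]];
    }
  return y;
}

// adaptive average pooling with floor/ceil bin edges
// [[Rcpp::export]]
NumericVector cpp_adavg_fw(NumericVector x, int Ho, int Wo) {
  int d[4]; get4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y = alloc4(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = (wo * W) / Wo, w1 = ((wo + 1) * W + Wo - 1) / Wo;
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = (ho * H) / Ho, h1 = ((ho + 1) * H + Ho - 1) / Ho;
          double s = 0.0;
          for (int w = w0; w < w1; ++w)
            for (int h = h0; h < h1; ++h) s += xp[h + (size_t)H * w];
          yp[ho + (size_t)Ho * wo] = s / ((h1 - h0) * (w1 - w0));
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_adavg_bw(NumericVector gy, int H, int W) {
  int d[4]; get4(gy, d);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector gx = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* gp = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* gyp = gy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = (wo * W) / Wo, w1 = ((wo + 1) * W + Wo - 1) / Wo;
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = (ho * H) / Ho, h1 = ((ho + 1) * H + Ho - 1) / Ho;
          const double g = gyp[ho + (size_t)Ho * wo] / ((h1 - h0) * (w1 - w0));
          for (int w = w0; w < w1; ++w)
            for (int h = h0; h < h1; ++h) gp[h + (size_t)H * w] += g;
        }
      }
    }
  return gx;
}

// global max pool to 1x1 with argmax (1-based linear index into x)
// [[Rcpp::export]]
List cpp_globalmax_fw(NumericVector x) {
  int d[4]; get4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y = alloc4(1, 1, C, N);
  IntegerVector idx(C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)H * W * (c + (size_t)C * n);
      const double* xp = x.begin() + off;
      double best = xp[0]; size_t bk = 0;
      for (size_t k = 1; k < (size_t)H * W; ++k)
        if (xp[k] > best) { best = xp[k]; bk = k; }
      y[c + (size_t)C * n] = best;
      idx[c + (size_t)C * n] = (int)(off + bk) + 1;
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// max over the channel axis with argmax channel
// [[Rcpp::export]]
List cpp_chanmax_fw(NumericVector x) {
  int d[4]; get4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y = alloc4(H, W, 1, N);
  IntegerVector idx = alloc4i(H, W, 1, N);
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + HW * C * (size_t)n;
    double* yp = y.begin() + HW * (size_t)n;
    int* ip = idx.begin() + HW * (size_t)n;
    for (size_t k = 0; k < HW; ++k) { yp[k] = xn[k]; ip[k] = 0; }
    for (int c = 1; c < C; ++c) {
      const double* xc = xn + HW * (size_t)c;
      for (size_t k = 0; k < HW; ++k)
        if (xc[k] > yp[k]) { yp[k] = xc[k]; ip[k] = c; }
    }
    // convert to 1-based linear index into x
    for (size_t k = 0; k < HW; ++k)
      ip[k] = (int)(k + HW * ((size_t)ip[k] + (size_t)C * n)) + 1;
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// k x k sliding mean with symmetric (reflective) padding, stride 1
// [[Rcpp::export]]
NumericMatrix cpp_box_mean_reflect(NumericMatrix x, int k) {
  const int H = x.nrow(), W = x.ncol(), r = k / 2;
  NumericMatrix tmp(H, W), y(H, W);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double s = 0.0;
      for (int i = -r; i <= r; ++i) s += x(reflect_idx(h + i, H), w);
      tmp(h, w) = s / k;
    }
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double s = 0.0;
      for (int j = -r; j <= r; ++j) s += tmp(h, reflect_idx(w + j, W));
      y(h, w) = s / k;
    }
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix x, double sigma) {
  const int H = x.nrow(), W = x.ncol();
  if (sigma <= 0) return clone(x);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + r];
  }
  for (double& v : ker) v /= s;
  NumericMatrix tmp(H, W), y(H, W);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double a = 0.0;
      for (int i = -r; i <= r; ++i) a += ker[i + r] * x(reflect_idx(h + i, H), w);
      tmp(h, w) = a;
    }
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double a = 0.0;
      for (int j = -r; j <= r; ++j) a += ker[j + r] * tmp(h, reflect_idx(w + j, W));
      y(h, w) = a;
    }
  return y;
}

// rotate a matrix about its centre; nearest-neighbour sampling,
// replicate-border for out-of-canvas sources
// [[Rcpp::export]]
NumericMatrix cpp_rotate_nearest(NumericMatrix x, double angle_deg) {
  const int H = x.nrow(), W = x.ncol();
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double ch = (H - 1) / 2.0, cw = (W - 1) / 2.0;
  NumericMatrix y(H, W);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      const double dh = h - ch, dw = w - cw;
      int hs = (int)std::lround(ct * dh - st * dw + ch);
      int ws = (int)std::lround(st * dh + ct * dw + cw);
      if (hs < 0) hs = 0; if (hs >= H) hs = H - 1;
      if (ws < 0) ws = 0; if (ws >= W) ws = W - 1;
      y(h, w) = x(hs, ws);
    }
  return y;
}
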