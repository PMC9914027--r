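// Low-level convolution and pooling kernels for 4-D activation arrays.
//
// Layout convention (R column-major):
//   activations  x : (H, W, C, N)
//   conv weights w : (kh, kw, C/groups, Cout)
// Grouped convolution splits both input and output channels into `groups`
// contiguous blocks; depthwise convolution is groups == C with Cout == C.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gather conv patches of one (sample, group) into a K x (Ho*Wo) matrix,
// K = kh*kw*Cg, row index a + kh*(b + kw*c) -- the column-major flattening
// of the weight kernel, so GEMM against reshaped weights is direct.
static void im2col(const double* x, int H, int W, int c0, int Cg,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& cols) {
  for (int cc = 0; cc < Cg; ++cc) {
    const double* xc = x + (size_t)(c0 + cc) * H * W;
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        const int row = a + kh * (b + kw * cc);
        for (int j = 0; j < Wo; ++j) {
          const int wsrc = j * stride - pad + b;
          if (wsrc < 0 || wsrc >= W) {
            for (int i = 0; i < Ho; ++i) cols(row, i + Ho * j) = 0.0;
            continue;
          }
          const double* xcw = xc + (size_t)wsrc * H;
          for (int i = 0; i < Ho; ++i) {
            const int hsrc = i * stride - pad + a;
            cols(row, i + Ho * j) = (hsrc < 0 || hsrc >= H) ? 0.0 : xcw[hsrc];
          }
        }
      }
    }
  }
}

// Scatter-add the inverse of im2col (gradient w.r.t. the input).
static void col2im(const arma::mat& cols, double* dx, int H, int W, int c0,
                   int Cg, int kh, int kw, int stride, int pad,
                   int Ho, int Wo) {
  for (int cc = 0; cc < Cg; ++cc) {
    double* xc = dx + (size_t)(c0 + cc) * H * W;
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        const int row = a + kh * (b + kw * cc);
        for (int j = 0; j < Wo; ++j) {
          const int wsrc = j * stride - pad + b;
          if (wsrc < 0 || wsrc >= W) continue;
          double* xcw = xc + (size_t)wsrc * H;
          for (int i = 0; i < Ho; ++i) {
            const int hsrc = i * stride - pad + a;
            if (hsrc >= 0 && hsrc < H) xcw[hsrc] += cols(row, i + Ho * j);
          }
        }
      }
    }
  }
}

// Depthwise (one kernel per channel) direct convolution, no im2col.
static void dw_fwd(const double* x, double* y, const double* w,
                   int H, int W, int C, int N, int kh, int kw,
                   int stride, int pad, int Ho, int Wo) {
  for (int cn = 0; cn < C * N; ++cn) {
    const int c = cn % C;
    const double* xc = x + (size_t)cn * H * W;
    double* yc = y + (size_t)cn * Ho * Wo;
    const double* wc = w + (size_t)c * kh * kw;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double acc = 0.0;
        for (int b = 0; b < kw; ++b) {
          const int ws = j * stride - pad + b;
          if (ws < 0 || ws >= W) continue;
          const double* xw = xc + (size_t)ws * H;
          const double* wb = wc + (size_t)b * kh;
          for (int a = 0; a < kh; ++a) {
            const int hs = i * stride - pad + a;
            if (hs >= 0 && hs < H) acc += xw[hs] * wb[a];
          }
        }
        yc[(size_t)j * Ho + i] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             int stride, int pad, int groups) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cg = wdim[2], Co = wdim[3];
  if (C / groups != Cg) stop("weight shape inconsistent with groups");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty");
  const int Cog = Co / groups;
  const int K = kh * kw * Cg;

  NumericVector y((size_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);

  if (groups == C && Cog == 1) {  // depthwise fast path
    dw_fwd(x.begin(), y.begin(), w.begin(), H, W, C, N, kh, kw,
           stride, pad, Ho, Wo);
    return y;
  }

  arma::mat cols(K, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, g * Cg, Cg, kh, kw, stride, pad, Ho, Wo, cols);
      const arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)g * Cog * K,
                         K, Cog, false, true);
      arma::mat Ym = Wm.t() * cols;  // Cog x (Ho*Wo)
      double* yp = y.begin() + (size_t)n * Ho * Wo * Co +
                   (size_t)g * Cog * Ho * Wo;
      for (int o = 0; o < Cog; ++o)
        for (size_t q = 0; q < (size_t)Ho * Wo; ++q)
          yp[(size_t)o * Ho * Wo + q] = Ym(o, q);
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector dy, int stride, int pad, int groups) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cg = wdim[2], Co = wdim[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int Cog = Co / groups;
  const int K = kh * kw * Cg;

  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  NumericVector dw((size_t)kh * kw * Cg * Co);
  dw.attr("dim") = wdim;

  if (groups == C && Co == C) {  // depthwise fast path
    for (int cn = 0; cn < C * N; ++cn) {
      const int c = cn % C;
      const double* xc = x.begin() + (size_t)cn * H * W;
      const double* gc = dy.begin() + (size_t)cn * Ho * Wo;
      double* dxc = dx.begin() + (size_t)cn * H * W;
      double* dwc = dw.begin() + (size_t)c * kh * kw;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          const double g = gc[(size_t)j * Ho + i];
          if (g == 0.0) continue;
          for (int b = 0; b < kw; ++b) {
            const int ws = j * stride - pad + b;
            if (ws < 0 || ws >= W) continue;
            for (int a = 0; a < kh; ++a) {
              const int hs = i * stride - pad + a;
              if (hs >= 0 && hs < H) {
                const size_t xi = (size_t)ws * H + hs;
                dwc[(size_t)b * kh + a] += g * xc[xi];
                dxc[xi] += g * w[(size_t)c * kh * kw + (size_t)b * kh + a];
              }
            }
          }
        }
      }
    }
    return List::create(Named("dx") = dx, Named("dw") = dw);
  }

  arma::mat cols(K, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    double* dxn = dx.begin() + (size_t)n * H * W * C;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, g * Cg, Cg, kh, kw, stride, pad, Ho, Wo, cols);
      const arma::mat dYt(const_cast<double*>(dy.begin()) +
                              (size_t)n * Ho * Wo * Co +
                              (size_t)g * Cog * Ho * Wo,
                          (size_t)Ho * Wo, Cog, false, true);
      arma::mat dWm(dw.begin() + (size_t)g * Cog * K, K, Cog, false, true);
      dWm += cols * dYt;
      const arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)g * Cog * K,
                         K, Cog, false, true);
      arma::mat dcols = Wm * dYt.t();  // K x (Ho*Wo)
      col2im(dcols, dxn, H, W, g * Cg, Cg, kh, kw, stride, pad, Ho, Wo);
    }
  }
  return List::create(Named("dx") = dx, Named("dw") = dw);
}

// 2x2 max pooling, stride 2. Returns pooled map and the argmax linear
// indices (0-based, into the input array) needed for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  if (H % 2 != 0 || W % 2 != 0)
    stop("maxpool2 requires even spatial dimensions, got %dx%d", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector am((size_t)Ho * Wo * C * N);

  size_t q = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xp = x.begin() + (size_t)cn * H * W;
    const size_t base = (size_t)cn * H * W;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int h0 = 2 * i, w0 = 2 * j;
        size_t best = (size_t)w0 * H + h0;
        double bv = xp[best];
        const size_t cand[3] = {(size_t)w0 * H + h0 + 1,
                                (size_t)(w0 + 1) * H + h0,
                                (size_t)(w0 + 1) * H + h0 + 1};
        for (int k = 0; k < 3; ++k)
          if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = cand[k]; }
        y[q] = bv;
        am[q] = (int)(base + best);
        ++q;
      }
    }
  }
  return List::create(Named("y") = y, Named("argmax") = am);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector argmax,
                               IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  const R_xlen_t n = dy.size();
  for (R_xlen_t q = 0; q < n; ++q) dx[argmax[q]] += dy[q];
  return dx;
}

// Per-column affine y = x * scale[j] + shift[j] for an (nrow x ncol)
// column-major matrix; one pass, no intermediate allocations.
// [[Rcpp::export]]
NumericVector cpp_col_affine(NumericVector x, int nrow,
                             NumericVector scale, NumericVector shift) {
  const R_xlen_t n = x.size();
  const int ncol = (int)(n / nrow);
  NumericVector y(n);
  for (int j = 0; j < ncol; ++j) {
    const double s = scale[j], t = shift[j];
    const double* xp = x.begin() + (size_t)j * nrow;
    double* yp = y.begin() + (size_t)j * nrow;
    for (int i = 0; i < nrow; ++i) yp[i] = xp[i] * s + t;
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// Per-column scale only.
// [[Rcpp::export]]
NumericVector cpp_col_scale(NumericVector x, int nrow, NumericVector scale) {
  const R_xlen_t n = x.size();
  const int ncol = (int)(n / nrow);
  NumericVector y(n);
  for (int j = 0; j < ncol; ++j) {
    const double s = scale[j];
    const double* xp = x.begin() + (size_t)j * nrow;
    double* yp = y.begin() + (size_t)j * nrow;
    for (int i = 0; i < nrow; ++i) yp[i] = xp[i] * s;
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// Exact GELU x * Phi(x); returns the activation and caches Phi(x).
// [[Rcpp::export]]
List cpp_gelu_fwd(NumericVector x) {
  const R_xlen_t n = x.size();
  NumericVector y(n), pn(n);
  const double inv_sqrt2 = 0.7071067811865475244;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double p = 0.5 * (1.0 + std::erf(x[i] * inv_sqrt2));
    pn[i] = p;
    y[i] = x[i] * p;
  }
  y.attr("dim") = x.attr("dim");
  return List::create(Named("y") = y, Named("pn") = pn);
}

// GELU gradient dy * (Phi(x) + x * phi(x)) from the cached CDF.
// [[Rcpp::export]]
NumericVector cpp_gelu_bwd(NumericVector dy, NumericVector x,
                           NumericVector pn) {
  const R_xlen_t n = x.size();
  NumericVector g(n);
  const double inv_sqrt2pi = 0.3989422804014326779;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double phi = inv_sqrt2pi * std::exp(-0.5 * x[i] * x[i]);
    g[i] = dy[i] * (pn[i] + x[i] * phi);
  }
  g.attr("dim") = dy.attr("dim");
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  const R_xlen_t n = x.size();
  NumericVector y(n);
  for (R_xlen_t i = 0; i < n; ++i) y[i] = x[i] > 0.0 ? x[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector x) {
  const R_xlen_t n = x.size();
  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = x[i] > 0.0 ? dy[i] : 0.0;
  g.attr("dim") = dy.attr("dim");
  return g;
}

// Extract channels [c0, c1] (1-based inclusive) of an (H, W, C, N) array.
// [[Rcpp::export]]
NumericVector cpp_chan_slice(NumericVector x, IntegerVector xdim,
                             int c0, int c1) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Cs = c1 - c0 + 1;
  const size_t plane = (size_t)H * W;
  NumericVector y(plane * Cs * N);
  y.attr("dim") = IntegerVector::create(H, W, Cs, N);
  for (int n = 0; n < N; ++n)
    std::memcpy(y.begin() + (size_t)n * plane * Cs,
                x.begin() + (size_t)n * plane * C + (size_t)(c0 - 1) * plane,
                sizeof(double) * plane * Cs);
  return y;
}

// Concatenate two channel blocks and optionally permute channels by perm
// (1-based input indices into the concatenated block).
// [[Rcpp::export]]
NumericVector cpp_chan_concat_perm(NumericVector a, NumericVector b,
                                   IntegerVector adim, IntegerVector bdim,
                                   IntegerVector perm) {
  const int H = adim[0], W = adim[1], Ca = adim[2], N = adim[3];
  const int Cb = bdim[2];
  const int C = Ca + Cb;
  const size_t plane = (size_t)H * W;
  NumericVector y(plane * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  const bool id = perm.size() == 0;
  for (int n = 0; n < N; ++n) {
    double* yn = y.begin() + (size_t)n * plane * C;
    const double* an = a.begin() + (size_t)n * plane * Ca;
    const double* bn = b.begin() + (size_t)n * plane * Cb;
    for (int c = 0; c < C; ++c) {
      const int src = id ? c : (perm[c] - 1);
      const double* s = src < Ca ? an + (size_t)src * plane
                                 : bn + (size_t)(src - Ca) * plane;
      std::memcpy(yn + (size_t)c * plane, s, sizeof(double) * plane);
    }
  }
  return y;
}

// Permute channels of an (H, W, C, N) array (1-based input indices).
// [[Rcpp::export]]
NumericVector cpp_chan_perm(NumericVector x, IntegerVector xdim,
                            IntegerVector perm) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t plane = (size_t)H * W;
  NumericVector y(plane * C * N);
  y.attr("dim") = xdim;
  for (int n = 0; n < N; ++n) {
    double* yn = y.begin() + (size_t)n * plane * C;
    const double* xn = x.begin() + (size_t)n * plane * C;
    for (int c = 0; c < C; ++c)
      std::memcpy(yn + (size_t)c * plane,
                  xn + (size_t)(perm[c] - 1) * plane, sizeof(double) * plane);
  }
  return y;
}

// colSums(a * b) for the implicit (nrow x ncol) views, without
// materializing the elementwise product.
// [[Rcpp::export]]
NumericVector cpp_colsums_prod(NumericVector a, NumericVector b, int nrow) {
  const R_xlen_t n = a.size();
  const int ncol = (int)(n / nrow);
  NumericVector s(ncol);
  for (int j = 0; j < ncol; ++j) {
    const double* ap = a.begin() + (size_t)j * nrow;
    const double* bp = b.begin() + (size_t)j * nrow;
    double acc = 0.0;
    for (int i = 0; i < nrow; ++i) acc += ap[i] * bp[i];
    s[j] = acc;
  }
  return s;
}
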