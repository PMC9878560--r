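#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Tensor layout throughout: column-major (H, W, C, N).
// linear index = h + H*(w + W*(c + C*n))

// Unfold x into a (kh*kw*C) x (Ho*Wo*N) matrix so convolution becomes a
// single matrix product (handled by BLAS on the R side).
// row = i + kh*(j + kw*c), col = ho + Ho*(wo + Wo*n)
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad, int dil) {
  int Ho = (H + 2 * pad - dil * (kh - 1) - 1) / stride + 1;
  int Wo = (W + 2 * pad - dil * (kw - 1) - 1) / stride + 1;
  NumericMatrix cols(kh * kw * C, Ho * Wo * N);
  double *pc = cols.begin();
  const double *px = x.begin();
  int K = kh * kw * C;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xc = px + (size_t)(c + (size_t)C * n) * H * W;
      for (int j = 0; j < kw; ++j) {
        for (int i = 0; i < kh; ++i) {
          int row = i + kh * (j + kw * c);
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride - pad + j * dil;
            if (wi < 0 || wi >= W) continue;
            double *dst = pc + (size_t)row +
              (size_t)K * (Ho * (wo + (size_t)Wo * n));
            const double *src = xc + (size_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + i * dil;
              if (hi < 0 || hi >= H) continue;
              dst[(size_t)K * ho] = src[hi];
            }
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-add columns back into the input shape.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad, int dil) {
  int Ho = (H + 2 * pad - dil * (kh - 1) - 1) / stride + 1;
  int Wo = (W + 2 * pad - dil * (kw - 1) - 1) / stride + 1;
  NumericVector x((size_t)H * W * C * N);
  double *px = x.begin();
  const double *pc = cols.begin();
  int K = kh * kw * C;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double *xc = px + (size_t)(c + (size_t)C * n) * H * W;
      for (int j = 0; j < kw; ++j) {
        for (int i = 0; i < kh; ++i) {
          int row = i + kh * (j + kw * c);
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride - pad + j * dil;
            if (wi < 0 || wi >= W) continue;
            const double *src = pc + (size_t)row +
              (size_t)K * (Ho * (wo + (size_t)Wo * n));
            double *dst = xc + (size_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + i * dil;
              if (hi < 0 || hi >= H) continue;
              dst[hi] += src[(size_t)K * ho];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}

// 2x2 max pooling, stride 2. Returns pooled values and the 1-based linear
// argmax indices into x (windows are disjoint, so the backward pass is a
// plain scatter).
// [[Rcpp::export]]
List maxpool2_cpp(NumericVector x, int H, int W, int C, int N) {
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  const double *px = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      size_t xoff = (size_t)(c + (size_t)C * n) * H * W;
      size_t yoff = (size_t)(c + (size_t)C * n) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          size_t base = xoff + (size_t)(2 * wo) * H + 2 * ho;
          size_t best = base;
          double bv = px[base];
          size_t cand[3] = {base + 1, base + H, base + H + 1};
          for (int t = 0; t < 3; ++t)
            if (px[cand[t]] > bv) { bv = px[cand[t]]; best = cand[t]; }
          size_t oi = yoff + (size_t)wo * Ho + ho;
          y[oi] = bv;
          idx[oi] = (int)best + 1;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Bilinear resize with half-pixel centers (align_corners = false).
// [[Rcpp::export]]
NumericVector bilinear_resize_cpp(NumericVector x, int H, int W, int C, int N,
                                  int Ho, int Wo) {
  NumericVector y((size_t)Ho * Wo * C * N);
  const double *px = x.begin();
  double *py = y.begin();
  double sh = (double)H / Ho, sw = (double)W / Wo;
  std::vector<int> h0(Ho), h1(Ho);
  std::vector<double> wh(Ho);
  for (int ho = 0; ho < Ho; ++ho) {
    double s = (ho + 0.5) * sh - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    h0[ho] = (int)std::floor(s);
    h1[ho] = std::min(h0[ho] + 1, H - 1);
    wh[ho] = s - h0[ho];
  }
  std::vector<int> w0(Wo), w1(Wo);
  std::vector<double> ww(Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    double s = (wo + 0.5) * sw - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    w0[wo] = (int)std::floor(s);
    w1[wo] = std::min(w0[wo] + 1, W - 1);
    ww[wo] = s - w0[wo];
  }
  size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double *xp = px + p * H * W;
    double *yp = py + p * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      const double *c0 = xp + (size_t)w0[wo] * H;
      const double *c1 = xp + (size_t)w1[wo] * H;
      double b = ww[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        double a = wh[ho];
        double v00 = c0[h0[ho]], v10 = c0[h1[ho]];
        double v01 = c1[h0[ho]], v11 = c1[h1[ho]];
        yp[(size_t)wo * Ho + ho] =
          (1 - a) * (1 - b) * v00 + a * (1 - b) * v10 +
          (1 - a) * b * v01 + a * b * v11;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// Adjoint of bilinear_resize_cpp: scatter output-space gradients back.
// [[Rcpp::export]]
NumericVector bilinear_resize_bwd_cpp(NumericVector g, int H, int W, int C,
                                      int N, int Ho, int Wo) {
  NumericVector dx((size_t)H * W * C * N);
  const double *pg = g.begin();
  double *pd = dx.begin();
  double sh = (double)H / Ho, sw = (double)W / Wo;
  std::vector<int> h0(Ho), h1(Ho);
  std::vector<double> wh(Ho);
  for (int ho = 0; ho < Ho; ++ho) {
    double s = (ho + 0.5) * sh - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    h0[ho] = (int)std::floor(s);
    h1[ho] = std::min(h0[ho] + 1, H - 1);
    wh[ho] = s - h0[ho];
  }
  std::vector<int> w0(Wo), w1(Wo);
  std::vector<double> ww(Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    double s = (wo + 0.5) * sw - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    w0[wo] = (int)std::floor(s);
    w1[wo] = std::min(w0[wo] + 1, W - 1);
    ww[wo] = s - w0[wo];
  }
  size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double *gp = pg + p * Ho * Wo;
    double *dp = pd + p * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      double b = ww[wo];
      double *c0 = dp + (size_t)w0[wo] * H;
      double *c1 = dp + (size_t)w1[wo] * H;
      for (int ho = 0; ho < Ho; ++ho) {
        double a = wh[ho];
        double gv = gp[(size_t)wo * Ho + ho];
        c0[h0[ho]] += (1 - a) * (1 - b) * gv;
        c0[h1[ho]] += a * (1 - b) * gv;
        c1[h0[ho]] += (1 - a) * b * gv;
        c1[h1[ho]] += a * b * gv;
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}
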