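// 2D convolution primitives for the dose-prediction network.
// Layout conventions (all column-major, matching R arrays):
//   activations x : (H, W, C, N)
//   weights     w : (kh, kw, Cin, Cout); as a matrix: (kh*kw*Cin) x Cout
//   im2col matrix : (Ho*Wo) x (kh*kw*Cin), row index = i + Ho*j
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int H, int k, int s, int p, int d) {
  return (H + 2 * p - d * (k - 1) - 1) / s + 1;
}

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   int dh, int dw, int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        double* dst = col.colptr(a + kh * b + kh * kw * c);
        for (int j = 0; j < Wo; ++j) {
          int wj = j * sw - pw + b * dw;
          if (wj < 0 || wj >= W) {
            std::fill(dst + (size_t)Ho * j, dst + (size_t)Ho * (j + 1), 0.0);
            continue;
          }
          const double* src = xc + (size_t)wj * H;
          double* d0 = dst + (size_t)Ho * j;
          for (int i = 0; i < Ho; ++i) {
            int hi = i * sh - ph + a * dh;
            d0[i] = (hi >= 0 && hi < H) ? src[hi] : 0.0;
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col
static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   int dh, int dw, int Ho, int Wo, double* x) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        const double* src = col.colptr(a + kh * b + kh * kw * c);
        for (int j = 0; j < Wo; ++j) {
          int wj = j * sw - pw + b * dw;
          if (wj < 0 || wj >= W) continue;
          double* dstc = xc + (size_t)wj * H;
          const double* s0 = src + (size_t)Ho * j;
          for (int i = 0; i < Ho; ++i) {
            int hi = i * sh - ph + a * dh;
            if (hi >= 0 && hi < H) dstc[hi] += s0[i];
          }
        }
      }
    }
  }
}

static NumericVector arr4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector iarr4(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  return d;
}

// [[Rcpp::export(name = ".cpp_conv_fwd")]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w,
                           int sh, int sw, int ph, int pw, int dh, int dw) {
  IntegerVector xd = dims4(x), wd = dims4(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch in conv forward");
  int Ho = out_size(H, kh, sh, ph, dh), Wo = out_size(W, kw, sw, pw, dw);
  if (Ho < 1 || Wo < 1) stop("conv output collapsed to zero size");
  NumericVector y = arr4(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat col((size_t)Ho * Wo, (size_t)kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C,
           kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo, col);
    arma::mat ym(y.begin() + (size_t)n * Ho * Wo * Cout,
                 (size_t)Ho * Wo, Cout, false, true);
    ym = col * Wm;
  }
  return y;
}

// gradient w.r.t. the conv input; also the forward pass of the
// fractionally-strided (transposed) convolution
// [[Rcpp::export(name = ".cpp_conv_bwd_data")]]
NumericVector cpp_conv_bwd_data(NumericVector dy, NumericVector w,
                                int sh, int sw, int ph, int pw,
                                int dh, int dw, int H, int W) {
  IntegerVector yd = dims4(dy), wd = dims4(w);
  int Ho = yd[0], Wo = yd[1], Cout = yd[2], N = yd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2];
  if (wd[3] != Cout) stop("channel mismatch in conv backward");
  if (out_size(H, kh, sh, ph, dh) != Ho || out_size(W, kw, sw, pw, dw) != Wo)
    stop("geometry mismatch in conv backward");
  NumericVector dx = arr4(H, W, Cin, N);
  arma::mat Wm(w.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat dym(dy.begin() + (size_t)n * Ho * Wo * Cout,
                  (size_t)Ho * Wo, Cout, false, true);
    arma::mat dcol = dym * Wm.t();
    col2im(dcol, H, W, Cin, kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo,
           dx.begin() + (size_t)n * H * W * Cin);
  }
  return dx;
}

// [[Rcpp::export(name = ".cpp_conv_bwd_filter")]]
NumericVector cpp_conv_bwd_filter(NumericVector x, NumericVector dy,
                                  int kh, int kw, int sh, int sw,
                                  int ph, int pw, int dh, int dw) {
  IntegerVector xd = dims4(x), yd = dims4(dy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = yd[0], Wo = yd[1], Cout = yd[2];
  if (yd[3] != N) stop("batch mismatch in filter gradient");
  NumericVector dw_ = arr4(kh, kw, C, Cout);
  arma::mat dWm(dw_.begin(), (size_t)kh * kw * C, Cout, false, true);
  arma::mat col((size_t)Ho * Wo, (size_t)kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C,
           kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo, col);
    arma::mat dym(dy.begin() + (size_t)n * Ho * Wo * Cout,
                  (size_t)Ho * Wo, Cout, false, true);
    dWm += col.t() * dym;
  }
  return dw_;
}

// [[Rcpp::export(name = ".cpp_maxpool_fwd")]]
List cpp_maxpool_fwd(NumericVector x, int k, int s, int p) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_size(H, k, s, p, 1), Wo = out_size(W, k, s, p, 1);
  NumericVector y = arr4(Ho, Wo, C, N);
  IntegerVector idx = iarr4(Ho, Wo, C, N);  // 0-based flat index into x
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      size_t off = ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          double best = -std::numeric_limits<double>::infinity();
          int barg = -1;
          for (int b = 0; b < k; ++b) {
            int wj = j * s - p + b;
            if (wj < 0 || wj >= W) continue;
            for (int a = 0; a < k; ++a) {
              int hi = i * s - p + a;
              if (hi < 0 || hi >= H) continue;
              double v = xc[hi + (size_t)wj * H];
              if (v > best) { best = v; barg = hi + wj * H; }
            }
          }
          y[off + i + (size_t)Ho * j] = (barg >= 0) ? best : 0.0;
          idx[off + i + (size_t)Ho * j] =
            (barg >= 0) ? (int)(((size_t)n * C + c) * H * W + barg) : -1;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool_bwd")]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx,
                              int H, int W) {
  IntegerVector yd = dims4(dy);
  int C = yd[2], N = yd[3];
  NumericVector dx = arr4(H, W, C, N);
  size_t M = dy.size();
  for (size_t t = 0; t < M; ++t)
    if (idx[t] >= 0) dx[idx[t]] += dy[t];
  return dx;
}
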