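// Low-level numeric kernels for the detector's convolutional engine.
// All feature maps are R arrays with dim (H, W, C, N), column-major.
// Convolution weights have dim (K, K, C_in/groups, C_out).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int h, int k, int stride, int pad) {
  return (h + 2 * pad - k) / stride + 1;
}

// Gather the im2col matrix for image n, channel group g.
// col is (K*K*CG) x (Ho*Wo); row index kh + K*kw + K*K*ci, col index oh + Ho*ow.
static void im2col(const double* x, arma::mat& col, int H, int W, int C,
                   int n, int g, int CG, int K, int stride, int pad,
                   int Ho, int Wo) {
  for (int ci = 0; ci < CG; ++ci) {
    const double* xc = x + (size_t)(n * C + g * CG + ci) * H * W;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        int row = kh + K * kw + K * K * ci;
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * stride - pad + kw;
          double* dst = col.memptr() + (size_t)row + (size_t)col.n_rows * (size_t)(Ho * ow);
          if (iw < 0 || iw >= W) {
            for (int oh = 0; oh < Ho; ++oh) { *dst = 0.0; dst += col.n_rows; }
            continue;
          }
          const double* xcol = xc + (size_t)iw * H;
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh * stride - pad + kh;
            *dst = (ih < 0 || ih >= H) ? 0.0 : xcol[ih];
            dst += col.n_rows;
          }
        }
      }
    }
  }
}

// Scatter-add of a col-shaped gradient back to the input image (col2im).
static void col2im(const arma::mat& col, double* gx, int H, int W, int C,
                   int n, int g, int CG, int K, int stride, int pad,
                   int Ho, int Wo) {
  for (int ci = 0; ci < CG; ++ci) {
    double* xc = gx + (size_t)(n * C + g * CG + ci) * H * W;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        int row = kh + K * kw + K * K * ci;
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * stride - pad + kw;
          if (iw < 0 || iw >= W) continue;
          double* xcol = xc + (size_t)iw * H;
          const double* src = col.memptr() + (size_t)row + (size_t)col.n_rows * (size_t)(Ho * ow);
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh * stride - pad + kh;
            if (ih >= 0 && ih < H) xcol[ih] += *src;
            src += col.n_rows;
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector bias, int stride, int pad,
                                 int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int K = wd[0], CG = wd[2], COUT = wd[3];
  if (C != CG * groups) stop("conv2d: channel mismatch (%d input, %d expected)", C, CG * groups);
  int COG = COUT / groups;
  int Ho = out_dim(H, K, stride, pad), Wo = out_dim(W, K, stride, pad);
  NumericVector y(Ho * Wo * COUT * (size_t)N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, COUT, N);
  bool has_bias = bias.size() > 0;
  arma::mat col(K * K * CG, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), col, H, W, C, n, g, CG, K, stride, pad, Ho, Wo);
      arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)g * COG * K * K * CG,
                   K * K * CG, COG, false, true);
      arma::mat Ym(y.begin() + (size_t)Ho * Wo * (n * COUT + g * COG),
                   Ho * Wo, COG, false, true);
      Ym = col.t() * Wm;
      if (has_bias)
        for (int co = 0; co < COG; ++co) Ym.col(co) += bias[g * COG + co];
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector gy,
                         int stride, int pad, int groups, bool need_gx,
                         bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int K = wd[0], CG = wd[2], COUT = wd[3];
  int COG = COUT / groups;
  int Ho = out_dim(H, K, stride, pad), Wo = out_dim(W, K, stride, pad);
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(has_bias ? COUT : 0);
  NumericVector gx(need_gx ? x.size() : 0);
  if (need_gx) gx.attr("dim") = xd;
  arma::mat col(K * K * CG, Ho * Wo), gcol(K * K * CG, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), col, H, W, C, n, g, CG, K, stride, pad, Ho, Wo);
      arma::mat GY(const_cast<double*>(gy.begin()) + (size_t)Ho * Wo * (n * COUT + g * COG),
                   Ho * Wo, COG, false, true);
      arma::mat GW(gw.begin() + (size_t)g * COG * K * K * CG, K * K * CG, COG, false, true);
      GW += col * GY;
      if (has_bias)
        for (int co = 0; co < COG; ++co) gb[g * COG + co] += arma::accu(GY.col(co));
      if (need_gx) {
        arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)g * COG * K * K * CG,
                     K * K * CG, COG, false, true);
        gcol = Wm * GY.t();
        col2im(gcol, gx.begin(), H, W, C, n, g, CG, K, stride, pad, Ho, Wo);
      }
    }
  }
  return List::create(_["gx"] = need_gx ? (SEXP)gx : R_NilValue,
                      _["gw"] = gw, _["gb"] = has_bias ? (SEXP)gb : R_NilValue);
}

// Same-size max pooling (stride 1, pad (k-1)/2), as used by SPPF.
// Returns the pooled map and the 1-based flat argmax index into x.
// [[Rcpp::export(name = ".maxpool_forward")]]
List maxpool_forward_cpp(NumericVector x, int k) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int pad = (k - 1) / 2;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  IntegerVector idx(x.size());
  const double* xp = x.begin();
  size_t off = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    const double* plane = xp + (size_t)cn * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double best = -INFINITY; size_t besti = 0;
        for (int dw = -pad; dw <= pad; ++dw) {
          int iw = w + dw;
          if (iw < 0 || iw >= W) continue;
          for (int dh = -pad; dh <= pad; ++dh) {
            int ih = h + dh;
            if (ih < 0 || ih >= H) continue;
            double v = plane[ih + (size_t)iw * H];
            if (v > best) { best = v; besti = (size_t)cn * H * W + ih + (size_t)iw * H; }
          }
        }
        y[off] = best;
        idx[off] = (int)(besti + 1);
        ++off;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_backward")]]
NumericVector maxpool_backward_cpp(IntegerVector idx, NumericVector gy,
                                   IntegerVector dims) {
  size_t n = (size_t)dims[0] * dims[1] * dims[2] * dims[3];
  NumericVector gx(n);
  gx.attr("dim") = dims;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  return gx;
}
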