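// Layer kernels for the compact SegNet. All tensors use the project-wide
// (batch, channel, height, width) dimension order; R stores these column-major
// so element (n,c,h,w) (0-based) sits at n + N*(c + C*(h + H*w)).
//
// Convolution is im2col + GEMM so the inner loop is a BLAS matrix product.
// The im2col column index p enumerates the spatial plane with h fastest
// (p = h + H*w), matching R's column-major plane layout; the row index is
// k = ci*9 + kh*3 + kw for kernel offsets (kh, kw) in {0,1,2}^2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline R_xlen_t tidx(int n, int c, int h, int w, int N, int C, int H) {
  return (R_xlen_t)n + (R_xlen_t)N * ((R_xlen_t)c + (R_xlen_t)C * ((R_xlen_t)h + (R_xlen_t)H * (R_xlen_t)w));
}

static void im2col_3x3(const double *x, int n, int N, int C, int H, int W,
                       arma::mat &col) {
  // col is (9*C) x (H*W); zero padding of one pixel on every side
  col.zeros();
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      const int p = h + H * w;
      for (int ci = 0; ci < C; ++ci) {
        for (int kh = 0; kh < 3; ++kh) {
          const int hi = h + kh - 1;
          if (hi < 0 || hi >= H) continue;
          for (int kw = 0; kw < 3; ++kw) {
            const int wi = w + kw - 1;
            if (wi < 0 || wi >= W) continue;
            col(ci * 9 + kh * 3 + kw, p) = x[tidx(n, ci, hi, wi, N, C, H)];
          }
        }
      }
    }
  }
}

static void col2im_3x3(const arma::mat &col, double *dx, int n, int N, int C,
                       int H, int W) {
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      const int p = h + H * w;
      for (int ci = 0; ci < C; ++ci) {
        for (int kh = 0; kh < 3; ++kh) {
          const int hi = h + kh - 1;
          if (hi < 0 || hi >= H) continue;
          for (int kw = 0; kw < 3; ++kw) {
            const int wi = w + kw - 1;
            if (wi < 0 || wi >= W) continue;
            dx[tidx(n, ci, hi, wi, N, C, H)] += col(ci * 9 + kh * 3 + kw, p);
          }
        }
      }
    }
  }
}

// weights array has dim (Cout, Cin, 3, 3): element (co,ci,kh,kw) at
// co + Cout*(ci + Cin*(kh + 3*kw))
static arma::mat weight_matrix(const NumericVector &wts, int Co, int Ci) {
  arma::mat Wm(Co, 9 * Ci);
  const double *w = REAL(wts);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int kh = 0; kh < 3; ++kh)
        for (int kw = 0; kw < 3; ++kw)
          Wm(co, ci * 9 + kh * 3 + kw) =
              w[co + (R_xlen_t)Co * (ci + (R_xlen_t)Ci * (kh + 3 * kw))];
  return Wm;
}

// [[Rcpp::export(name = ".conv2d_forward_cpp")]]
NumericVector conv2d_forward_cpp(NumericVector x, IntegerVector xdim,
                                 NumericVector wts, int Co, int Ci,
                                 NumericVector bias) {
  const int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  if (C != Ci) stop("channel mismatch: input has %d channels, kernels expect %d", C, Ci);
  arma::mat Wm = weight_matrix(wts, Co, Ci);
  NumericVector y((R_xlen_t)N * Co * H * W);
  arma::mat col(9 * Ci, (R_xlen_t)H * W);
  const double *xp = REAL(x);
  double *yp = REAL(y);
  for (int n = 0; n < N; ++n) {
    im2col_3x3(xp, n, N, C, H, W, col);
    arma::mat out = Wm * col;  // Co x (H*W)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const int p = h + H * w;
        for (int co = 0; co < Co; ++co)
          yp[tidx(n, co, h, w, N, Co, H)] = out(co, p) + bias[co];
      }
  }
  y.attr("dim") = IntegerVector::create(N, Co, H, W);
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward_cpp")]]
List conv2d_backward_cpp(NumericVector x, IntegerVector xdim, NumericVector wts,
                         int Co, int Ci, NumericVector dy) {
  const int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  if (C != Ci) stop("channel mismatch in conv backward");
  arma::mat Wm = weight_matrix(wts, Co, Ci);
  arma::mat dWm(Co, 9 * Ci, arma::fill::zeros);
  NumericVector dx((R_xlen_t)N * C * H * W);
  NumericVector db(Co);
  arma::mat col(9 * Ci, (R_xlen_t)H * W);
  arma::mat dym(Co, (R_xlen_t)H * W);
  const double *xp = REAL(x);
  const double *dyp = REAL(dy);
  double *dxp = REAL(dx);
  for (int n = 0; n < N; ++n) {
    im2col_3x3(xp, n, N, C, H, W, col);
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const int p = h + H * w;
        for (int co = 0; co < Co; ++co)
          dym(co, p) = dyp[tidx(n, co, h, w, N, Co, H)];
      }
    dWm += dym * col.t();
    for (int co = 0; co < Co; ++co) db[co] += arma::accu(dym.row(co));
    arma::mat colgrad = Wm.t() * dym;  // (9*Ci) x (H*W)
    col2im_3x3(colgrad, dxp, n, N, C, H, W);
  }
  NumericVector dW((R_xlen_t)Co * Ci * 9);
  double *dwp = REAL(dW);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int kh = 0; kh < 3; ++kh)
        for (int kw = 0; kw < 3; ++kw)
          dwp[co + (R_xlen_t)Co * (ci + (R_xlen_t)Ci * (kh + 3 * kw))] =
              dWm(co, ci * 9 + kh * 3 + kw);
  dx.attr("dim") = xdim;
  dW.attr("dim") = IntegerVector::create(Co, Ci, 3, 3);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 stride-2 max pooling. Indices are 1-based flat positions in the input
// (H x W) plane, column-major with h fastest: pos = h + H*(w-1) for 1-based
// (h, w). Ties keep the first maximum in row-major window order
// (top-left, top-right, bottom-left, bottom-right).
// [[Rcpp::export(name = ".maxpool_forward_cpp")]]
List maxpool_forward_cpp(NumericVector x, IntegerVector xdim) {
  const int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  if (H % 2 != 0 || W % 2 != 0)
    stop("max pooling requires even spatial dimensions, got %d x %d", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)N * C * Ho * Wo);
  IntegerVector idx((R_xlen_t)N * C * Ho * Wo);
  const double *xp = REAL(x);
  double *yp = REAL(y);
  int *ip = INTEGER(idx);
  const int dh[4] = {0, 0, 1, 1};
  const int dw[4] = {0, 1, 0, 1};
  for (int w = 0; w < Wo; ++w)
    for (int h = 0; h < Ho; ++h)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double best = R_NegInf;
          int bestpos = 0;
          for (int k = 0; k < 4; ++k) {
            const int hi = 2 * h + dh[k], wi = 2 * w + dw[k];
            const double v = xp[tidx(n, c, hi, wi, N, C, H)];
            if (v > best) { best = v; bestpos = (hi + 1) + H * wi; }
          }
          const R_xlen_t o = tidx(n, c, h, w, N, C, Ho);
          yp[o] = best;
          ip[o] = bestpos;
        }
  y.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  idx.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  return List::create(_["values"] = y, _["indices"] = idx);
}

// Scatter pooled values back to their memorized argmax positions; zeros
// elsewhere. Also serves as the max-pool backward pass (scatter of dy).
// [[Rcpp::export(name = ".maxunpool_cpp")]]
NumericVector maxunpool_cpp(NumericVector x, IntegerVector xdim,
                            IntegerVector idx, int Ho, int Wo) {
  const int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  if (Ho != 2 * H || Wo != 2 * W)
    stop("output shape %d x %d does not match a 2x2 unpool of %d x %d", Ho, Wo, H, W);
  NumericVector y((R_xlen_t)N * C * Ho * Wo);
  const double *xp = REAL(x);
  const int *ip = INTEGER(idx);
  double *yp = REAL(y);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          const R_xlen_t o = tidx(n, c, h, w, N, C, H);
          const int pos = ip[o];
          const int hi = (pos - 1) % Ho;       // 0-based row in output plane
          const int wi = (pos - 1) / Ho;       // 0-based column
          if (hi / 2 != h || wi / 2 != w)
            stop("pool index %d lies outside its 2x2 window (output cell %d,%d)",
                 pos, h + 1, w + 1);
          yp[tidx(n, c, hi, wi, N, C, Ho)] = xp[o];
        }
  y.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  return y;
}

// Gather: backward pass of max-unpooling (gradient w.r.t. the pooled input).
// [[Rcpp::export(name = ".unpool_backward_cpp")]]
NumericVector unpool_backward_cpp(NumericVector dy, IntegerVector ydim,
                                  IntegerVector idx, IntegerVector xdim) {
  const int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int Ho = ydim[2];
  NumericVector dx((R_xlen_t)N * C * H * W);
  const double *dyp = REAL(dy);
  const int *ip = INTEGER(idx);
  double *dxp = REAL(dx);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          const R_xlen_t o = tidx(n, c, h, w, N, C, H);
          const int pos = ip[o];
          const int hi = (pos - 1) % Ho;
          const int wi = (pos - 1) / Ho;
          dxp[o] = dyp[tidx(n, c, hi, wi, N, C, Ho)];
        }
  dx.attr("dim") = xdim;
  return dx;
}

// Batch-norm kernels: single-pass per-channel statistics and normalization
// over the (batch, height, width) positions of each channel.

// [[Rcpp::export(name = ".bn_stats_cpp")]]
List bn_stats_cpp(NumericVector x, IntegerVector xdim) {
  const int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  NumericVector mean(C), var(C);
  const double *xp = REAL(x);
  const R_xlen_t plane_n = (R_xlen_t)N;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double *base = xp + tidx(0, c, h, w, N, C, H);
        for (R_xlen_t n = 0; n < plane_n; ++n) { s += base[n]; s2 += base[n] * base[n]; }
      }
    const double m = (double)N * H * W;
    mean[c] = s / m;
    double v = s2 / m - mean[c] * mean[c];
    var[c] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export(name = ".bn_apply_cpp")]]
List bn_apply_cpp(NumericVector x, IntegerVector xdim, NumericVector mean,
                  NumericVector invstd, NumericVector gamma,
                  NumericVector beta, bool want_xhat) {
  const int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  NumericVector y(x.size());
  NumericVector xhat = want_xhat ? NumericVector(x.size()) : NumericVector(0);
  const double *xp = REAL(x);
  double *yp = REAL(y);
  double *hp = want_xhat ? REAL(xhat) : nullptr;
  for (int c = 0; c < C; ++c) {
    const double mu = mean[c], is = invstd[c], g = gamma[c], b = beta[c];
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const R_xlen_t off = tidx(0, c, h, w, N, C, H);
        for (int n = 0; n < N; ++n) {
          const double xh = (xp[off + n] - mu) * is;
          if (hp) hp[off + n] = xh;
          yp[off + n] = g * xh + b;
        }
      }
  }
  y.attr("dim") = xdim;
  if (want_xhat) xhat.attr("dim") = xdim;
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// train-mode backward: dx = invstd*gamma*(dy - s2/m - xhat*s1/m) with
// s1 = sum(dy*xhat), s2 = sum(dy) per channel; infer-mode drops the
// statistic terms. dgamma = s1, dbeta = s2.
// [[Rcpp::export(name = ".bn_backward_cpp")]]
List bn_backward_cpp(NumericVector dy, NumericVector xhat, IntegerVector xdim,
                     NumericVector gamma, NumericVector invstd, bool train) {
  const int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  const double *dp = REAL(dy);
  const double *hp = REAL(xhat);
  double *op = REAL(dx);
  const double m = (double)N * H * W;
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const R_xlen_t off = tidx(0, c, h, w, N, C, H);
        for (int n = 0; n < N; ++n) { s1 += dp[off + n] * hp[off + n]; s2 += dp[off + n]; }
      }
    dgamma[c] = s1; dbeta[c] = s2;
    const double gi = gamma[c] * invstd[c];
    const double a1 = train ? s2 / m : 0.0, a2 = train ? s1 / m : 0.0;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const R_xlen_t off = tidx(0, c, h, w, N, C, H);
        for (int n = 0; n < N; ++n)
          op[off + n] = gi * (dp[off + n] - a1 - hp[off + n] * a2);
      }
  }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
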