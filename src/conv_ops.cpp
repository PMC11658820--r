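// Low-level kernels for the convolutional engine.
//
// Feature maps are (H*W) x C matrices in R's column-major pixel order:
// row index = y + H*x for 0-based pixel (y = image row, x = image column).
// A batch of nimg images is ONE matrix: image n occupies the contiguous row
// block [n*H*W, (n+1)*H*W).
//
// Convolutions use stride 1 and 'same' zero padding. The patch (im2col)
// matrix is never materialized for a whole image: patches are gathered into
// a small column-blocked buffer that is fed straight to BLAS dgemm, keeping
// the working set cache-sized. The weight layout is a (k^2*C_in) x C_out
// matrix whose rows are ordered channel-major, kernel tap j = (dx+r)*k+(dy+r)
// fastest within a channel.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cstring>
#include <vector>
#include <algorithm>

#ifndef FCONE
#define FCONE
#endif

using Rcpp::NumericMatrix;
using Rcpp::NumericVector;
using Rcpp::IntegerMatrix;

// Gather the patch rows for output image-columns [x0, x0+bx) of one image
// into buf (H*bx rows, k*k*C cols). xptr points at the image's own rows.
static void im2col_block(const double* xptr, R_xlen_t ldx, int H, int W,
                         int k, int C, int x0, int bx, double* buf) {
  const int r = k / 2;
  const R_xlen_t m = (R_xlen_t)H * bx;
  std::memset(buf, 0, sizeof(double) * m * (size_t)k * k * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = xptr + ldx * c;
    for (int dx = -r; dx <= r; ++dx) {
      for (int dy = -r; dy <= r; ++dy) {
        const int j = (dx + r) * k + (dy + r);
        double* bc = buf + m * ((size_t)c * k * k + j);
        const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        if (y1 <= y0) continue;
        for (int xb = 0; xb < bx; ++xb) {
          const int xs = x0 + xb + dx;
          if (xs < 0 || xs >= W) continue;
          std::memcpy(bc + (R_xlen_t)H * xb + y0,
                      xc + (R_xlen_t)H * xs + (y0 + dy),
                      sizeof(double) * (size_t)(y1 - y0));
        }
      }
    }
  }
}

// Adjoint: scatter-add the patch-gradient block back onto dX.
static void col2im_block(const double* buf, R_xlen_t ldo, int H, int W,
                         int k, int C, int x0, int bx, double* optr) {
  const int r = k / 2;
  const R_xlen_t m = (R_xlen_t)H * bx;
  for (int c = 0; c < C; ++c) {
    double* oc = optr + ldo * c;
    for (int dx = -r; dx <= r; ++dx) {
      for (int dy = -r; dy <= r; ++dy) {
        const int j = (dx + r) * k + (dy + r);
        const double* bc = buf + m * ((size_t)c * k * k + j);
        const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        if (y1 <= y0) continue;
        for (int xb = 0; xb < bx; ++xb) {
          const int xs = x0 + xb + dx;
          if (xs < 0 || xs >= W) continue;
          double* dst = oc + (R_xlen_t)H * xs + (y0 + dy);
          const double* src = bc + (R_xlen_t)H * xb + y0;
          for (int y = 0; y < y1 - y0; ++y) dst[y] += src[y];
        }
      }
    }
  }
}

static int pick_block(int H, int W, int kkC) {
  // target a ~4 MB gather buffer
  int bx = (int)(500000.0 / ((double)H * kkC));
  return std::max(1, std::min(W, bx));
}

// Forward convolution: Y = conv(X) with weights Wt ((k^2*C_in) x C_out).
// [[Rcpp::export]]
NumericMatrix conv_fw(const NumericMatrix& X, const NumericMatrix& Wt,
                      int H, int W, int k, int nimg) {
  const int C = X.ncol(), Cout = Wt.ncol();
  const int kkC = k * k * C;
  const R_xlen_t HW = (R_xlen_t)H * W, rows = HW * nimg;
  if (X.nrow() != rows) Rcpp::stop("conv_fw: nrow(X) != H*W*nimg");
  if (Wt.nrow() != kkC) Rcpp::stop("conv_fw: nrow(Wt) != k^2*C_in");
  NumericMatrix Y(rows, Cout);
  const int bx = pick_block(H, W, kkC);
  std::vector<double> buf((size_t)H * bx * kkC);
  const double one = 1.0, zero = 0.0;
  const int ldy = (int)rows;
  for (int n = 0; n < nimg; ++n) {
    const double* xptr = &X(0, 0) + HW * n;
    for (int x0 = 0; x0 < W; x0 += bx) {
      const int bw = std::min(bx, W - x0);
      const int m = H * bw;
      im2col_block(xptr, rows, H, W, k, C, x0, bw, buf.data());
      double* yptr = &Y(0, 0) + HW * n + (R_xlen_t)H * x0;
      F77_CALL(dgemm)("N", "N", &m, &Cout, &kkC, &one, buf.data(), &m,
                      &Wt(0, 0), &kkC, &zero, yptr, &ldy FCONE FCONE);
    }
  }
  return Y;
}

// Backward convolution: given dY, accumulate dW = d(patches)^T dY and
// (optionally) the input gradient dX = scatter(dY Wt^T).
// [[Rcpp::export]]
Rcpp::List conv_bw(const NumericMatrix& X, const NumericMatrix& Wt,
                   const NumericMatrix& dY, int H, int W, int k, int nimg,
                   bool need_dx) {
  const int C = X.ncol(), Cout = Wt.ncol();
  const int kkC = k * k * C;
  const R_xlen_t HW = (R_xlen_t)H * W, rows = HW * nimg;
  if (X.nrow() != rows || dY.nrow() != rows || dY.ncol() != Cout ||
      Wt.nrow() != kkC)
    Rcpp::stop("conv_bw: inconsistent dimensions");
  NumericMatrix dW(kkC, Cout);
  NumericMatrix dX(need_dx ? rows : 1, need_dx ? C : 1);
  const int bx = pick_block(H, W, kkC);
  std::vector<double> buf((size_t)H * bx * kkC);
  std::vector<double> buf2(need_dx ? (size_t)H * bx * kkC : 1);
  const double one = 1.0, zero = 0.0;
  const int ld = (int)rows;
  for (int n = 0; n < nimg; ++n) {
    const double* xptr = &X(0, 0) + HW * n;
    for (int x0 = 0; x0 < W; x0 += bx) {
      const int bw = std::min(bx, W - x0);
      const int m = H * bw;
      const double* dyptr = &dY(0, 0) + HW * n + (R_xlen_t)H * x0;
      im2col_block(xptr, rows, H, W, k, C, x0, bw, buf.data());
      F77_CALL(dgemm)("T", "N", &kkC, &Cout, &m, &one, buf.data(), &m,
                      dyptr, &ld, &one, &dW(0, 0), &kkC FCONE FCONE);
      if (need_dx) {
        F77_CALL(dgemm)("N", "T", &m, &kkC, &Cout, &one, dyptr, &ld,
                        &Wt(0, 0), &kkC, &zero, buf2.data(), &m FCONE FCONE);
        col2im_block(buf2.data(), rows, H, W, k, C, x0, bw,
                     &dX(0, 0) + HW * n);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("dX") = need_dx ? dX : NumericMatrix(0, 0));
}

// 2x2 max pooling with stride 2 (trailing row/column dropped when odd).
// Returns pooled values and 1-based argmax row indices into the input
// (global, i.e. including the image's row offset); windows are disjoint so
// the backward pass is a plain scatter.
// [[Rcpp::export]]
Rcpp::List maxpool2(const NumericMatrix& X, int H, int W, int nimg = 1) {
  const int C = X.ncol(), Ho = H / 2, Wo = W / 2;
  const R_xlen_t HW = (R_xlen_t)H * W, HWo = (R_xlen_t)Ho * Wo;
  if (X.nrow() != HW * nimg) Rcpp::stop("maxpool2: nrow(X) != H*W*nimg");
  NumericMatrix Y(HWo * nimg, C);
  IntegerMatrix A(HWo * nimg, C);
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < nimg; ++n) {
      const double* xc = &X(0, c) + HW * n;
      double* yc = &Y(0, c) + HWo * n;
      int* ac = &A(0, c) + HWo * n;
      for (int x = 0; x < Wo; ++x) {
        for (int y = 0; y < Ho; ++y) {
          const R_xlen_t base = (R_xlen_t)(2 * x) * H + 2 * y;
          R_xlen_t idx[4] = {base, base + 1, base + H, base + H + 1};
          R_xlen_t best = idx[0];
          for (int t = 1; t < 4; ++t) if (xc[idx[t]] > xc[best]) best = idx[t];
          yc[(R_xlen_t)y + (R_xlen_t)Ho * x] = xc[best];
          ac[(R_xlen_t)y + (R_xlen_t)Ho * x] = (int)(best + 1 + HW * n);
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y, Rcpp::Named("argmax") = A);
}

// Scatter pooled gradients back: dX[argmax[i,c], c] = dY[i, c].
// [[Rcpp::export]]
NumericMatrix maxpool2_backward(const NumericMatrix& dY, const IntegerMatrix& A,
                                int H, int W, int nimg = 1) {
  const int C = dY.ncol();
  NumericMatrix out((R_xlen_t)H * W * nimg, C);
  for (int c = 0; c < C; ++c) {
    const double* dc = &dY(0, c);
    const int* ac = &A(0, c);
    double* oc = &out(0, c);
    const R_xlen_t n = dY.nrow();
    for (R_xlen_t i = 0; i < n; ++i) oc[ac[i] - 1] += dc[i];
  }
  return out;
}

// Nearest-neighbour upsampling by an integer factor, and its adjoint
// (f x f sum pooling).
// [[Rcpp::export]]
NumericMatrix upsample_nn(const NumericMatrix& X, int H, int W, int f,
                          int nimg = 1) {
  const int C = X.ncol(), Ho = H * f, Wo = W * f;
  const R_xlen_t HW = (R_xlen_t)H * W, HWo = (R_xlen_t)Ho * Wo;
  if (X.nrow() != HW * nimg) Rcpp::stop("upsample_nn: nrow(X) != H*W*nimg");
  NumericMatrix out(HWo * nimg, C);
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < nimg; ++n) {
      const double* xc = &X(0, c) + HW * n;
      double* oc = &out(0, c) + HWo * n;
      for (int xo = 0; xo < Wo; ++xo) {
        const double* src = xc + (R_xlen_t)H * (xo / f);
        double* dst = oc + (R_xlen_t)Ho * xo;
        for (int yo = 0; yo < Ho; ++yo) dst[yo] = src[yo / f];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix upsample_nn_backward(const NumericMatrix& dY, int H, int W, int f,
                                   int nimg = 1) {
  const int C = dY.ncol(), Ho = H * f, Wo = W * f;
  const R_xlen_t HW = (R_xlen_t)H * W, HWo = (R_xlen_t)Ho * Wo;
  if (dY.nrow() != HWo * nimg) Rcpp::stop("upsample_nn_backward: bad nrow");
  NumericMatrix out(HW * nimg, C);
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < nimg; ++n) {
      const double* dc = &dY(0, c) + HWo * n;
      double* oc = &out(0, c) + HW * n;
      for (int xo = 0; xo < Wo; ++xo) {
        double* dst = oc + (R_xlen_t)H * (xo / f);
        const double* src = dc + (R_xlen_t)Ho * xo;
        for (int yo = 0; yo < Ho; ++yo) dst[yo / f] += src[yo];
      }
    }
  }
  return out;
}

// out[i, c] = x[i, c] * a[c] + b[c], optionally clamped at 0 (fused
// batch-norm affine + ReLU).
// [[Rcpp::export]]
NumericMatrix scale_shift(const NumericMatrix& X, const NumericVector& a,
                          const NumericVector& b, bool relu = false) {
  const int C = X.ncol();
  const R_xlen_t n = X.nrow();
  NumericMatrix out(n, C);
  for (int c = 0; c < C; ++c) {
    const double ac = a[c], bc = b[c];
    const double* xc = &X(0, c);
    double* oc = &out(0, c);
    if (relu) {
      for (R_xlen_t i = 0; i < n; ++i) {
        const double v = xc[i] * ac + bc;
        oc[i] = v > 0 ? v : 0;
      }
    } else {
      for (R_xlen_t i = 0; i < n; ++i) oc[i] = xc[i] * ac + bc;
    }
  }
  return out;
}

// Fused batch-norm input gradient:
// dx[i,c] = (dy[i,c] * gamma[c] - s1m[c] - xhat[i,c] * s2m[c]) * istd[c].
// [[Rcpp::export]]
NumericMatrix bn_backward_dx(const NumericMatrix& dY, const NumericVector& gamma,
                             const NumericMatrix& xhat,
                             const NumericVector& s1m, const NumericVector& s2m,
                             const NumericVector& istd) {
  const int C = dY.ncol();
  const R_xlen_t n = dY.nrow();
  NumericMatrix out(n, C);
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c], s1 = s1m[c], s2 = s2m[c], is = istd[c];
    const double* dc = &dY(0, c);
    const double* xc = &xhat(0, c);
    double* oc = &out(0, c);
    for (R_xlen_t i = 0; i < n; ++i) oc[i] = (dc[i] * g - s1 - xc[i] * s2) * is;
  }
  return out;
}

// Fused backward through ReLU and batch normalization in one kernel.
// Given the gradient d arriving at the ReLU output, the pre-normalization
// conv output Z and the batch-norm parameters, computes (without
// materializing xhat or the masked gradient):
//   dbeta[c]  = sum_i mask_i d_i
//   dgamma[c] = sum_i mask_i d_i xhat_i
//   dx[i,c]   = (mask_i d_i g - g dbeta/m - xhat_i g dgamma/m) istd
// where xhat_i = (z_i - mu) istd and mask_i = (g xhat_i + beta > 0).
// [[Rcpp::export]]
Rcpp::List bn_relu_backward(const NumericMatrix& d, const NumericMatrix& Z,
                            const NumericVector& gamma, const NumericVector& beta,
                            const NumericVector& mu, const NumericVector& istd,
                            double m_total) {
  const int C = d.ncol();
  const R_xlen_t n = d.nrow();
  NumericMatrix out(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c], be = beta[c], m = mu[c], is = istd[c];
    const double A = g * is, B = be - m * A;
    const double* dc = &d(0, c);
    const double* zc = &Z(0, c);
    double s1 = 0, s2 = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      if (zc[i] * A + B > 0) {
        s1 += dc[i];
        s2 += dc[i] * (zc[i] - m) * is;
      }
    }
    dbeta[c] = s1; dgamma[c] = s2;
    const double t1 = g * s1 / m_total, t2 = g * s2 / m_total;
    double* oc = &out(0, c);
    for (R_xlen_t i = 0; i < n; ++i) {
      const double xh = (zc[i] - m) * is;
      const double dm = (zc[i] * A + B > 0) ? dc[i] * g : 0.0;
      oc[i] = (dm - t1 - xh * t2) * is;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = out,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// Column sums of A, and of the elementwise product A*B, in one pass
// (batch-norm scale/shift gradients without materializing A*B).
// [[Rcpp::export]]
Rcpp::List colsums_pair(const NumericMatrix& A, const NumericMatrix& B) {
  const int C = A.ncol();
  const R_xlen_t n = A.nrow();
  NumericVector sa(C), sab(C);
  for (int c = 0; c < C; ++c) {
    const double* ac = &A(0, c);
    const double* bc = &B(0, c);
    double s1 = 0, s2 = 0;
    for (R_xlen_t i = 0; i < n; ++i) { s1 += ac[i]; s2 += ac[i] * bc[i]; }
    sa[c] = s1; sab[c] = s2;
  }
  return Rcpp::List::create(Rcpp::Named("sum") = sa, Rcpp::Named("sum_prod") = sab);
}

// ReLU backward through a batch-norm affine without materializing the
// activation: out[i,c] = dY[i,c] if z[i,c]*a[c]+b[c] > 0 else 0.
// [[Rcpp::export]]
NumericMatrix relu_backward_affine(const NumericMatrix& dY, const NumericMatrix& Z,
                                   const NumericVector& a, const NumericVector& b) {
  const int C = dY.ncol();
  const R_xlen_t n = dY.nrow();
  NumericMatrix out(n, C);
  for (int c = 0; c < C; ++c) {
    const double ac = a[c], bc = b[c];
    const double* dc = &dY(0, c);
    const double* zc = &Z(0, c);
    double* oc = &out(0, c);
    for (R_xlen_t i = 0; i < n; ++i) {
      oc[i] = (zc[i] * ac + bc > 0) ? dc[i] : 0;
    }
  }
  return out;
}
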