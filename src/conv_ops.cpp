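// 3x3 same-padding convolution kernels used by the small segmentation and
// regression networks. Tensors are dense R arrays laid out [H, W, C, N]
// (column-major, H fastest). Weights are a (C*9) x O matrix whose rows are
// ordered channel-major then (dj, di) over the 3x3 window; this matches the
// im2col layout below.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Unfold one image [H, W, C] into a (C*9) x (H*W) patch matrix with
// clamp-to-edge padding. Row index = c*9 + (dj+1)*3 + (di+1). Edge padding
// (rather than zero padding) keeps the convolution of an affinely shifted
// image an exact per-channel affine everywhere, including the border —
// which the test-time-adaptation invariance relies on.
static inline int clampi(int v, int hi) {
  return v < 0 ? 0 : (v >= hi ? hi - 1 : v);
}

static arma::mat im2col3(const double* x, const int H, const int W, const int C) {
  arma::mat col(C * 9, H * W);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int r = c * 9 + (dj + 1) * 3 + (di + 1);
        for (int j = 0; j < W; ++j) {
          const double* src = xc + (size_t)clampi(j + dj, W) * H;
          double* dst = col.memptr() + (size_t)(j * H) * (C * 9) + r;
          for (int i = 0; i < H; ++i) {
            dst[(size_t)i * (C * 9)] = src[clampi(i + di, H)];
          }
        }
      }
    }
  }
  return col;
}

// Fold a (C*9) x (H*W) gradient matrix back onto an image gradient [H, W, C]
// (accumulating), the adjoint of im2col3.
static void col2im3(const arma::mat& col, double* dx, const int H, const int W,
                    const int C) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int r = c * 9 + (dj + 1) * 3 + (di + 1);
        for (int j = 0; j < W; ++j) {
          double* dst = xc + (size_t)clampi(j + dj, W) * H;
          const double* src = col.memptr() + (size_t)(j * H) * (C * 9) + r;
          for (int i = 0; i < H; ++i) {
            dst[clampi(i + di, H)] += src[(size_t)i * (C * 9)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3_fwd")]]
NumericVector conv3_fwd(NumericVector x, NumericMatrix Wm, NumericVector b) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("x must be a 4-d array [H,W,C,N]");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int O = Wm.ncol();
  if (Wm.nrow() != C * 9) stop("weight rows must equal C*9");
  const arma::mat Wa(Wm.begin(), C * 9, O, false);
  const arma::vec ba(b.begin(), O, false);
  NumericVector y((R_xlen_t)H * W * O * N);
  y.attr("dim") = IntegerVector::create(H, W, O, N);
  const size_t P = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col3(x.begin() + (size_t)n * P * C, H, W, C);
    arma::mat yn(y.begin() + (size_t)n * P * O, P, O, false, true);
    yn = col.t() * Wa;
    yn.each_row() += ba.t();
  }
  return y;
}

// [[Rcpp::export(name = ".conv3_bwd")]]
List conv3_bwd(NumericVector x, NumericMatrix Wm, NumericVector dy) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int O = Wm.ncol();
  const arma::mat Wa(Wm.begin(), C * 9, O, false);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericMatrix dW(C * 9, O);
  NumericVector db(O);
  arma::mat dWa(dW.begin(), C * 9, O, false, true);
  arma::vec dba(db.begin(), O, false, true);
  const size_t P = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col3(x.begin() + (size_t)n * P * C, H, W, C);
    const arma::mat dyn(const_cast<double*>(dy.begin()) + (size_t)n * P * O, P,
                        O, false);
    dWa += col * dyn;
    dba += arma::sum(dyn, 0).t();
    arma::mat dcol = Wa * dyn.t();
    col2im3(dcol, dx.begin() + (size_t)n * P * C, H, W, C);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
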