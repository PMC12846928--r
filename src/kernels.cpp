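#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Feature-map layout used throughout: a batch of B images of size H x W with C
// channels is a (B*H*W) x C matrix. Rows are ordered image-major, then
// column-major within an image (row index i fastest), matching as.vector() of
// an R H x W matrix.

static void im2col3(const arma::mat& X, arma::mat& col, int B, int H, int W) {
  const int Cin = X.n_cols;
  for (int c = 0; c < Cin; ++c) {
    const double* xc = X.colptr(c);
    for (int k = 0; k < 9; ++k) {
      const int dy = k % 3 - 1, dx = k / 3 - 1;
      double* dst = col.colptr(c * 9 + k);
      for (int img = 0; img < B; ++img) {
        const double* xi = xc + (size_t)img * H * W;
        double* di = dst + (size_t)img * H * W;
        for (int j = 0; j < W; ++j) {
          const int js = j + dx;
          if (js < 0 || js >= W) {
            for (int i = 0; i < H; ++i) di[j * H + i] = 0.0;
            continue;
          }
          const double* src = xi + (size_t)js * H;
          for (int i = 0; i < H; ++i) {
            const int is = i + dy;
            di[j * H + i] = (is < 0 || is >= H) ? 0.0 : src[is];
          }
        }
      }
    }
  }
}

// Scatter-add the column matrix back onto the input grid (adjoint of im2col3).
static void col2im3(const arma::mat& col, arma::mat& dX, int B, int H, int W) {
  const int Cin = dX.n_cols;
  for (int c = 0; c < Cin; ++c) {
    double* xc = dX.colptr(c);
    for (int k = 0; k < 9; ++k) {
      const int dy = k % 3 - 1, dx = k / 3 - 1;
      const double* src = col.colptr(c * 9 + k);
      for (int img = 0; img < B; ++img) {
        double* xi = xc + (size_t)img * H * W;
        const double* si = src + (size_t)img * H * W;
        for (int j = 0; j < W; ++j) {
          const int js = j + dx;
          if (js < 0 || js >= W) continue;
          double* dstc = xi + (size_t)js * H;
          for (int i = 0; i < H; ++i) {
            const int is = i + dy;
            if (is >= 0 && is < H) dstc[is] += si[j * H + i];
          }
        }
      }
    }
  }
}

// 3x3 same-padding convolution. W3 is (9*Cin) x Cout with kernel offsets
// fastest within each input channel.
// [[Rcpp::export]]
arma::mat conv3_fwd(const arma::mat& X, const arma::mat& W3, const arma::vec& b,
                    int B, int H, int W) {
  arma::mat col((size_t)B * H * W, W3.n_rows);
  im2col3(X, col, B, H, W);
  arma::mat Y = col * W3;
  Y.each_row() += b.t();
  return Y;
}

// [[Rcpp::export]]
List conv3_bwd(const arma::mat& X, const arma::mat& dY, const arma::mat& W3,
               int B, int H, int W) {
  arma::mat col((size_t)B * H * W, W3.n_rows);
  im2col3(X, col, B, H, W);
  arma::mat dW = col.t() * dY;
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat dcol = dY * W3.t();
  arma::mat dX((size_t)B * H * W, X.n_cols, arma::fill::zeros);
  col2im3(dcol, dX, B, H, W);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2 (H, W even). Returns pooled map and the winning
// input row (1-based) per output element for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd(const arma::mat& X, int B, int H, int W) {
  const int C = X.n_cols, Ho = H / 2, Wo = W / 2;
  arma::mat Y((size_t)B * Ho * Wo, C);
  arma::imat amax((size_t)B * Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double* yc = Y.colptr(c);
    arma::sword* ac = amax.colptr(c);
    for (int img = 0; img < B; ++img) {
      const size_t in0 = (size_t)img * H * W, out0 = (size_t)img * Ho * Wo;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          size_t best = in0 + (size_t)(2 * j) * H + 2 * i;
          double bv = xc[best];
          const size_t cand[3] = {best + 1, best + H, best + H + 1};
          for (int q = 0; q < 3; ++q)
            if (xc[cand[q]] > bv) { bv = xc[cand[q]]; best = cand[q]; }
          yc[out0 + (size_t)j * Ho + i] = bv;
          ac[out0 + (size_t)j * Ho + i] = (arma::sword)best + 1;
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["amax"] = amax);
}

// [[Rcpp::export]]
arma::mat maxpool2_bwd(const arma::mat& dY, const arma::imat& amax, int Nin) {
  const int C = dY.n_cols;
  arma::mat dX(Nin, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* dyc = dY.colptr(c);
    const arma::sword* ac = amax.colptr(c);
    double* dxc = dX.colptr(c);
    for (size_t r = 0; r < dY.n_rows; ++r) dxc[ac[r] - 1] += dyc[r];
  }
  return dX;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
arma::mat upsample2_fwd(const arma::mat& X, int B, int H, int W) {
  const int C = X.n_cols, Ho = 2 * H, Wo = 2 * W;
  arma::mat Y((size_t)B * Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double* yc = Y.colptr(c);
    for (int img = 0; img < B; ++img) {
      const size_t in0 = (size_t)img * H * W, out0 = (size_t)img * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i)
          yc[out0 + (size_t)j * Ho + i] = xc[in0 + (size_t)(j / 2) * H + i / 2];
    }
  }
  return Y;
}

// [[Rcpp::export]]
arma::mat upsample2_bwd(const arma::mat& dY, int B, int H, int W) {
  // H, W refer to the (smaller) input grid of the forward pass.
  const int C = dY.n_cols, Ho = 2 * H, Wo = 2 * W;
  arma::mat dX((size_t)B * H * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* dyc = dY.colptr(c);
    double* dxc = dX.colptr(c);
    for (int img = 0; img < B; ++img) {
      const size_t in0 = (size_t)img * H * W, out0 = (size_t)img * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i)
          dxc[in0 + (size_t)(j / 2) * H + i / 2] += dyc[out0 + (size_t)j * Ho + i];
    }
  }
  return dX;
}
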