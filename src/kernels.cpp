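// Dense numeric kernels for the CNN: stride-1 "same" 2-D convolution via
// im2col, and 2x2 max pooling with argmax bookkeeping for backprop.
// Feature maps are arma::cube (H rows, W cols, C slices), which shares
// memory layout with an R array of dim c(H, W, C).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// Patch rows are ordered (di fastest, then dj, then input channel), matching
// the vectorisation of an R weight array dim c(k, k, Cin, Cout).
static mat im2col_same(const cube &X, const int k) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int p = (k - 1) / 2, kk = k * k;
  mat cols(kk * C, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int row = c * kk + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - p;
            if (si < 0 || si >= H) continue;
            cols(row, (size_t)j * H + i) = X(si, sj, c);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube &X, const arma::mat &Wm,
                      const arma::vec &b, const int k) {
  const int H = X.n_rows, W = X.n_cols;
  const int Cout = Wm.n_cols;
  mat cols = im2col_same(X, k);
  mat Y = cols.t() * Wm;          // (H*W) x Cout
  Y.each_row() += b.t();
  return cube(Y.memptr(), H, W, Cout);
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube &X, const arma::mat &Wm,
                      const arma::cube &dY, const int k) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int Cout = dY.n_slices, p = (k - 1) / 2, kk = k * k;
  const mat dYm(const_cast<double *>(dY.memptr()), (size_t)H * W, Cout, false);
  mat cols = im2col_same(X, k);
  mat dW = cols * dYm;            // (k*k*C) x Cout
  vec db = sum(dYm, 0).t();
  mat dcols = Wm * dYm.t();       // (k*k*C) x (H*W)
  cube dX(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int row = c * kk + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - p;
            if (si < 0 || si >= H) continue;
            dX(si, sj, c) += dcols(row, (size_t)j * H + i);
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dX, _["dw"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2; odd trailing row/col is dropped (floor).
// idx holds 1-based linear indices into X for gradient routing.
// [[Rcpp::export]]
Rcpp::List maxpool2_fwd(const arma::cube &X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube Y(Ho, Wo, C);
  cube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf;
        size_t bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int si = 2 * i + di, sj = 2 * j + dj;
            const double v = X(si, sj, c);
            if (v > best) {
              best = v;
              bi = (size_t)c * H * W + (size_t)sj * H + si;
            }
          }
        }
        Y(i, j, c) = best;
        idx(i, j, c) = (double)(bi + 1);
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::cube &dY, const arma::cube &idx,
                        const int H, const int W, const int C) {
  cube dX(H, W, C, fill::zeros);
  const size_t n = dY.n_elem;
  for (size_t t = 0; t < n; ++t) {
    dX((size_t)idx(t) - 1) += dY(t);
  }
  return dX;
}
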