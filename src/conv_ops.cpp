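// Minimal conv-net kernels: im2col convolution forward/backward and max-pooling.
// Tensor layout: arma::cube (H, W, C); weights: mat (C_out, kh*kw*C_in) with
// column index k = ((c * kh + dy) * kw + dx); spatial columns are packed
// column-major over output positions, p = j * Hout + i.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static mat im2col(const cube& x, int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  mat cols(kh * kw * C, Ho * Wo, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dy = 0; dy < kh; ++dy) {
      for (int dx = 0; dx < kw; ++dx) {
        const int k = (c * kh + dy) * kw + dx;
        for (int j = 0; j < Wo; ++j) {
          const int xj = j * stride + dx - pad;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int xi = i * stride + dy - pad;
            if (xi < 0 || xi >= H) continue;
            cols(k, j * Ho + i) = x(xi, xj, c);
          }
        }
      }
    }
  }
  return cols;
}

static cube col2im(const mat& cols, int H, int W, int C,
                   int kh, int kw, int stride, int pad) {
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dy = 0; dy < kh; ++dy) {
      for (int dx = 0; dx < kw; ++dx) {
        const int k = (c * kh + dy) * kw + dx;
        for (int j = 0; j < Wo; ++j) {
          const int xj = j * stride + dx - pad;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int xi = i * stride + dy - pad;
            if (xi < 0 || xi >= H) continue;
            x(xi, xj, c) += cols(k, j * Ho + i);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube nn_conv_fwd(const arma::cube& x, const arma::mat& w,
                       const arma::vec& b, int kh, int kw,
                       int stride, int pad) {
  const int Ho = out_dim(x.n_rows, kh, stride, pad);
  const int Wo = out_dim(x.n_cols, kw, stride, pad);
  mat cols = im2col(x, kh, kw, stride, pad);
  mat out = w * cols;            // (C_out, Ho*Wo)
  out.each_col() += b;
  cube y(Ho, Wo, w.n_rows);
  for (uword c = 0; c < w.n_rows; ++c)
    y.slice(c) = reshape(out.row(c).t(), Ho, Wo);
  return y;
}

// [[Rcpp::export]]
Rcpp::List nn_conv_bwd(const arma::cube& x, const arma::mat& w,
                       const arma::cube& gy, int kh, int kw,
                       int stride, int pad) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, Co = gy.n_slices;
  mat gout(Co, Ho * Wo);
  for (int c = 0; c < Co; ++c)
    gout.row(c) = vectorise(gy.slice(c)).t();
  mat cols = im2col(x, kh, kw, stride, pad);
  mat gw = gout * cols.t();
  vec gb = sum(gout, 1);
  mat gcols = w.t() * gout;
  cube gx = col2im(gcols, x.n_rows, x.n_cols, x.n_slices, kh, kw, stride, pad);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
Rcpp::List nn_maxpool_fwd(const arma::cube& x, int k, int stride) {
  const int Ho = (x.n_rows - k) / stride + 1;
  const int Wo = (x.n_cols - k) / stride + 1;
  const int C = x.n_slices;
  cube y(Ho, Wo, C);
  ucube amax(Ho, Wo, C);  // linear index into the input slice
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf; uword arg = 0;
        for (int dx = 0; dx < k; ++dx) {
          for (int dy = 0; dy < k; ++dy) {
            const int xi = i * stride + dy, xj = j * stride + dx;
            const double v = x(xi, xj, c);
            if (v > best) { best = v; arg = xj * x.n_rows + xi; }
          }
        }
        y(i, j, c) = best;
        amax(i, j, c) = arg;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("amax") = amax);
}

// [[Rcpp::export]]
arma::cube nn_maxpool_bwd(const arma::ucube& amax, const arma::cube& gy,
                          int H, int W) {
  cube gx(H, W, gy.n_slices, fill::zeros);
  for (uword c = 0; c < gy.n_slices; ++c)
    for (uword j = 0; j < gy.n_cols; ++j)
      for (uword i = 0; i < gy.n_rows; ++i)
        gx.slice(c)(amax(i, j, c)) += gy(i, j, c);
  return gx;
}
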