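// Convolution primitives for the residual dense subnetworks and the
// Gaussian-derivative filtering used by the vesselness module.
//
// Layout conventions (column-major, matching R arrays):
//   images/activations: arma::cube H x W x C; the cube memory is identical
//                       to an (H*W) x C matrix, which is exploited below
//   conv weights:       arma::mat Cout x (k*k*Cin); within a row the
//                       column order is (ki, kj, cin) fastest-to-slowest
// Stride is always 1 and padding is "same" (zero) with odd kernel size k.
// im2col uses the transposed (H*W) x (k*k*Cin) layout so that every patch
// column can be filled with contiguous memcpy runs.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void im2col_t(const cube& x, const int k, mat& out) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = k / 2;
  out.zeros(H * W, k * k * C);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + k * kj + k * k * c;
        const int di = ki - p, dj = kj - p;
        double* dst0 = out.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          if (i0 >= i1) continue;
          std::memcpy(dst0 + j * H + i0,
                      x.slice_colptr(c, sj) + i0 + di,
                      sizeof(double) * (i1 - i0));
        }
      }
    }
  }
}

static void col2im_t_add(cube& x, const mat& cols, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = k / 2;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + k * kj + k * k * c;
        const int di = ki - p, dj = kj - p;
        const double* src0 = cols.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          if (i0 >= i1) continue;
          double* dst = x.slice_colptr(c, sj) + di;
          const double* src = src0 + j * H;
          for (int i = i0; i < i1; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_rows;
  cube out(H, W, Cout);
  mat ym(out.memptr(), H * W, Cout, false, true);
  if (k == 1) {
    const mat xm(const_cast<double*>(x.memptr()), H * W, x.n_slices,
                 false, true);
    ym = xm * w.t();
  } else {
    mat cols;
    im2col_t(x, k, cols);
    ym = cols * w.t();
  }
  ym.each_row() += b.t();
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                          const arma::cube& dy, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  const mat dym(const_cast<double*>(dy.memptr()), H * W, Cout, false, true);
  vec db = sum(dym, 0).t();
  mat dw;
  cube dx(H, W, Cin, fill::zeros);
  if (k == 1) {
    const mat xm(const_cast<double*>(x.memptr()), H * W, Cin, false, true);
    dw = dym.t() * xm;
    mat dxm(dx.memptr(), H * W, Cin, false, true);
    dxm = dym * w;
  } else {
    mat cols;
    im2col_t(x, k, cols);
    dw = dym.t() * cols;
    mat dcols = dym * w;  // (H*W) x (k*k*Cin)
    col2im_t_add(dx, dcols, k);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// Separable 2-D correlation with replicate boundary handling, used for
// Gaussian smoothing and Gaussian-derivative (Hessian) filtering.
// kr is applied along rows (i.e. down columns), kc along columns.
// [[Rcpp::export]]
arma::mat cpp_sepfilter2(const arma::mat& x, const arma::vec& kr,
                         const arma::vec& kc) {
  const int H = x.n_rows, W = x.n_cols;
  const int rr = (kr.n_elem - 1) / 2, rc = (kc.n_elem - 1) / 2;
  mat tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int t = -rr; t <= rr; ++t) {
        int ii = std::min(std::max(i + t, 0), H - 1);
        acc += kr(t + rr) * x(ii, j);
      }
      tmp(i, j) = acc;
    }
  }
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int t = -rc; t <= rc; ++t) {
        int jj = std::min(std::max(j + t, 0), W - 1);
        acc += kc(t + rc) * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  }
  return out;
}
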