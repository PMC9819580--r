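// Core tensor primitives for the small fully-convolutional networks used in
// this package.  Layout convention: activations are 4-D arrays (H, W, C, N)
// in R's column-major order, so slice n is an (H, W, C) cube.  Convolutions
// are "same"-padded, stride 1, with optional dilation; pooling is 2x2/2.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::cube slice_cube(const NumericVector& x, int H, int W, int C, int n) {
  // zero-copy view of sample n
  return arma::cube(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                    H, W, C, false, true);
}

// Build im2col matrix: (k*k*Cin) x (H*W), same padding, dilation d.
static void im2col(const arma::cube& x, int k, int d, arma::mat& M) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = ((k - 1) * d) / 2;
  M.zeros(k * k * C, H * W);
  for (int c = 0; c < C; ++c) {
    for (int kb = 0; kb < k; ++kb) {        // kernel col
      for (int ka = 0; ka < k; ++ka) {      // kernel row
        const int row = ka + k * (kb + k * c);
        const int oa = ka * d - pad, ob = kb * d - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + ob;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + oa;
            if (si < 0 || si >= H) continue;
            M(row, i + H * j) = x(si, sj, c);
          }
        }
      }
    }
  }
}

// Scatter-add the columns of M back onto an image (adjoint of im2col).
static void col2im(const arma::mat& M, int k, int d, arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = ((k - 1) * d) / 2;
  for (int c = 0; c < C; ++c) {
    for (int kb = 0; kb < k; ++kb) {
      for (int ka = 0; ka < k; ++ka) {
        const int row = ka + k * (kb + k * c);
        const int oa = ka * d - pad, ob = kb * d - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + ob;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + oa;
            if (si < 0 || si >= H) continue;
            x(si, sj, c) += M(row, i + H * j);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, IntegerVector xdim,
                         NumericVector w, int k, int cin, int cout,
                         NumericVector b, int dilation) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  if (C != cin) stop("conv2d: channel mismatch");
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * cin, cout, false, true);
  arma::vec bv(const_cast<double*>(b.begin()), cout, false, true);
  NumericVector y((size_t)H * W * cout * N);
  arma::mat M;
  for (int n = 0; n < N; ++n) {
    arma::cube xs = slice_cube(x, H, W, C, n);
    im2col(xs, k, dilation, M);
    arma::mat Ym(y.begin() + (size_t)n * H * W * cout, H * W, cout, false, true);
    Ym = M.t() * Wm;
    Ym.each_row() += bv.t();
  }
  y.attr("dim") = IntegerVector::create(H, W, cout, N);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, IntegerVector xdim,
                NumericVector w, int k, int cin, int cout,
                NumericVector dy, int dilation, bool need_dx, bool need_dw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * cin, cout, false, true);
  NumericVector dx(need_dx ? (size_t)H * W * C * N : 0);
  arma::mat dW(k * k * cin, cout, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  arma::mat M;
  for (int n = 0; n < N; ++n) {
    arma::mat dYm(const_cast<double*>(dy.begin()) + (size_t)n * H * W * cout,
                  H * W, cout, false, true);
    if (need_dw) {
      arma::cube xs = slice_cube(x, H, W, C, n);
      im2col(xs, k, dilation, M);
      dW += M * dYm;
      db += arma::sum(dYm, 0).t();
    }
    if (need_dx) {
      arma::mat Mx = Wm * dYm.t();   // (k*k*cin) x (H*W)
      arma::cube dxs(dx.begin() + (size_t)n * H * W * C, H, W, C, false, true);
      col2im(Mx, k, dilation, dxs);
    }
  }
  if (need_dx) dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dx"] = dx,
                      _["dw"] = NumericVector(dW.begin(), dW.end()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial dims must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);   // linear index into x
  size_t p = 0;
  for (int n = 0; n < N; ++n) {
    const size_t off = (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          double best = -1e300; size_t bidx = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              size_t q = off + (size_t)(2 * i + di) + (size_t)H * ((2 * j + dj) + (size_t)W * c);
              if (x[q] > best) { best = x[q]; bidx = q; }
            }
          y[p] = best; idx[p] = (int)bidx; ++p;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t p = 0; p < dy.size(); ++p) dx[idx[p]] += dy[p];
  dx.attr("dim") = xdim;
  return dx;
}
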