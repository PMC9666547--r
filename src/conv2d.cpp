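// 2D convolution kernels (same padding, stride 1) used by the network trunk.
// Layout: feature maps are H x W x C cubes; a k x k filter bank is stored as a
// (k*k*Cin) x Cout matrix whose rows follow im2col order (dy, dx, cin).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col with zero padding p = (k-1)/2; output is (H*W) x (k*k*Cin),
// column-major over output pixels (i fastest), matching R's array order.
static mat im2col(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (k - 1) / 2;
  mat out(H * W, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int col = c * k * k + dx * k + dy;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dx - p;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + dy - p;
            if (si < 0 || si >= H) continue;
            out(j * H + i, col) = x(si, sj, c);
          }
        }
      }
    }
  }
  return out;
}

// adjoint of im2col: scatter-add columns back onto the padded image
static cube col2im(const mat& cols, const int H, const int W, const int C,
                   const int k) {
  const int p = (k - 1) / 2;
  cube out(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int col = c * k * k + dx * k + dy;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dx - p;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + dy - p;
            if (si < 0 || si >= H) continue;
            out(si, sj, c) += cols(j * H + i, col);
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv2dForward")]]
arma::cube conv2dForward(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  mat cols = im2col(x, k);
  mat y = cols * w;             // (H*W) x Cout
  y.each_row() += b.t();
  cube out(H, W, Cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export(name = ".conv2dBackward")]]
Rcpp::List conv2dBackward(const arma::cube& x, const arma::cube& dout,
                          const arma::mat& w, const int k,
                          const bool need_dx) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dout.n_slices;
  mat cols = im2col(x, k);
  mat dy(const_cast<double*>(dout.memptr()), H * W, Cout, false, true);
  mat dw = cols.t() * dy;
  vec db = sum(dy, 0).t();
  cube dx;
  if (need_dx) {
    mat dcols = dy * w.t();
    dx = col2im(dcols, H, W, Cin, k);
  } else {
    dx = cube(1, 1, 1, fill::zeros);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}
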