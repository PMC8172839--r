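// im2col-based 2-D convolution primitives (stride 1, same zero padding)
// backing the package's small fully convolutional network.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// column layout: index = (c * k + i) * k + j for input channel c,
// kernel row offset i, kernel col offset j (offsets 0..k-1, pad (k-1)/2)
static mat im2col(const cube& x, int k) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int pad = (k - 1) / 2;
  mat cols(h * w, k * k * cin, fill::zeros);
  for (int c = 0; c < cin; ++c) {
    const mat& plane = x.slice(c);
    for (int i = 0; i < k; ++i) {
      for (int j = 0; j < k; ++j) {
        const int col_idx = (c * k + i) * k + j;
        const int dy = i - pad, dx = j - pad;
        // destination rows are (row r, col cc) -> r + cc*h
        const int r0 = std::max(0, -dy), r1 = std::min(h, h - dy);
        const int c0 = std::max(0, -dx), c1 = std::min(w, w - dx);
        if (r1 <= r0 || c1 <= c0) continue;
        for (int cc = c0; cc < c1; ++cc) {
          std::memcpy(cols.colptr(col_idx) + cc * h + r0,
                      plane.colptr(cc + dx) + r0 + dy,
                      sizeof(double) * (r1 - r0));
        }
      }
    }
  }
  return cols;
}

static cube col2im(const mat& gcols, int h, int w, int cin, int k) {
  const int pad = (k - 1) / 2;
  cube gx(h, w, cin, fill::zeros);
  for (int c = 0; c < cin; ++c) {
    mat& plane = gx.slice(c);
    for (int i = 0; i < k; ++i) {
      for (int j = 0; j < k; ++j) {
        const int col_idx = (c * k + i) * k + j;
        const int dy = i - pad, dx = j - pad;
        const int r0 = std::max(0, -dy), r1 = std::min(h, h - dy);
        const int c0 = std::max(0, -dx), c1 = std::min(w, w - dx);
        if (r1 <= r0 || c1 <= c0) continue;
        for (int cc = c0; cc < c1; ++cc) {
          double* dst = plane.colptr(cc + dx) + r0 + dy;
          const double* src = gcols.colptr(col_idx) + cc * h + r0;
          for (int r = 0; r < r1 - r0; ++r) dst[r] += src[r];
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube conv2d_forward(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int k) {
  const int h = x.n_rows, w = x.n_cols, cout = W.n_cols;
  mat cols = im2col(x, k);
  mat out = cols * W;
  out.each_row() += b.t();
  cube res(h, w, cout);
  std::memcpy(res.memptr(), out.memptr(), sizeof(double) * out.n_elem);
  return res;
}

// [[Rcpp::export]]
Rcpp::List conv2d_backward(const arma::cube& x, const arma::mat& W,
                           const arma::cube& gout, int k) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int cout = gout.n_slices;
  mat cols = im2col(x, k);
  mat gmat(const_cast<double*>(gout.memptr()), h * w, cout, false, true);
  mat gW = cols.t() * gmat;
  vec gb = sum(gmat, 0).t();
  mat gcols = gmat * W.t();
  cube gx = col2im(gcols, h, w, cin, k);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}
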