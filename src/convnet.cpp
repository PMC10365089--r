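// Minimal 2-D convolution kernels for the CSD networks.
// Layout conventions: images are H x W x C cubes (column-major, matching R
// arrays); convolution weights are (k*k*c_in) x c_out matrices with patch
// entries ordered (row-in-kernel, col-in-kernel, channel); zero padding.

#include <RcppArmadillo.h>
#ifndef _WIN32
#include <dlfcn.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Pin the process BLAS to one thread when OpenBLAS is in use: multithreaded
// GEMM reassociates sums nondeterministically under load, which would break
// the bit-identical-training contract.
// [[Rcpp::export]]
bool blas_single_thread() {
#ifndef _WIN32
  typedef void (*setter)(int);
  setter f = reinterpret_cast<setter>(dlsym(RTLD_DEFAULT,
                                            "openblas_set_num_threads"));
  if (f != nullptr) {
    f(1);
    return true;
  }
#endif
  return false;
}

static mat im2col(const cube& x, int k, int stride, int pad,
                  int h_out, int w_out) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(h_out * w_out, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int p = ki + kj * k + c * k * k;
        for (int oj = 0; oj < w_out; ++oj) {
          const int j = oj * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < h_out; ++oi) {
            const int i = oi * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            cols(oi + oj * h_out, p) = x(i, j, c);
          }
        }
      }
    }
  }
  return cols;
}

static void dims_out(const cube& x, int k, int stride, int pad,
                     int& h_out, int& w_out) {
  h_out = (static_cast<int>(x.n_rows) + 2 * pad - k) / stride + 1;
  w_out = (static_cast<int>(x.n_cols) + 2 * pad - k) / stride + 1;
  if (h_out < 1 || w_out < 1)
    Rcpp::stop("input smaller than kernel after padding");
}

// [[Rcpp::export]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, int k, int stride, int pad) {
  int h_out, w_out;
  dims_out(x, k, stride, pad, h_out, w_out);
  const int c_out = w.n_cols;
  if (static_cast<int>(w.n_rows) != k * k * static_cast<int>(x.n_slices))
    Rcpp::stop("weight shape does not match kernel/channels");
  mat cols = im2col(x, k, stride, pad, h_out, w_out);
  mat out = cols * w;
  out.each_row() += b.t();
  cube y(h_out, w_out, c_out);
  std::memcpy(y.memptr(), out.memptr(), sizeof(double) * out.n_elem);
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bw(const arma::cube& x, const arma::mat& w,
                     const arma::cube& gout, int k, int stride, int pad) {
  int h_out, w_out;
  dims_out(x, k, stride, pad, h_out, w_out);
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int c_out = w.n_cols;
  mat cols = im2col(x, k, stride, pad, h_out, w_out);
  mat gmat(h_out * w_out, c_out);
  std::memcpy(gmat.memptr(), gout.memptr(), sizeof(double) * gmat.n_elem);
  mat gw = cols.t() * gmat;
  vec gb = sum(gmat, 0).t();
  mat gcols = gmat * w.t();
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int p = ki + kj * k + c * k * k;
        for (int oj = 0; oj < w_out; ++oj) {
          const int j = oj * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < h_out; ++oi) {
            const int i = oi * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            gx(i, j, c) += gcols(oi + oj * h_out, p);
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}
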