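// Convolution primitives backing the autograd engine.
//
// Tensor layout (R side): 4-D array with dim c(H, W, C, N), column-major,
// so one sample's channel plane is contiguous and a sample is an
// (H*W x C) matrix when viewed column-major.
//
// Weight layouts:
//   conv:            dim c(k, k, Cin, Cout)  -> arma::mat (k*k*Cin, Cout)
//   transposed conv: dim c(k, k, Cout, Cin)  -> arma::mat (k*k*Cout, Cin)
//
// The im2col row ordering (ki fastest, then kj, then channel) matches the
// weight memory layout, so forward/backward reduce to GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   arma::mat& cols) {
  // cols: (k*k*C) x (Ho*Wo), output pixel index l = oi + Ho*oj
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int r = ki + k * (kj + k * c);
        for (int oj = 0; oj < Wo; ++oj) {
          int jj = oj * stride - pad + kj;
          if (jj < 0 || jj >= W) continue;
          const double* xcol = xc + (std::size_t)jj * H;
          double* cc = cols.colptr(0) + r; // row r, walk columns
          for (int oi = 0; oi < Ho; ++oi) {
            int ii = oi * stride - pad + ki;
            if (ii < 0 || ii >= H) continue;
            cc[(std::size_t)(oi + Ho * oj) * cols.n_rows] = xcol[ii];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& cols, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   double* x) {
  // inverse scatter-add of im2col; x has H*W*C entries (one sample)
  for (int c = 0; c < C; ++c) {
    double* xc = x + (std::size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int r = ki + k * (kj + k * c);
        for (int oj = 0; oj < Wo; ++oj) {
          int jj = oj * stride - pad + kj;
          if (jj < 0 || jj >= W) continue;
          double* xcol = xc + (std::size_t)jj * H;
          const double* cc = cols.colptr(0) + r;
          for (int oi = 0; oi < Ho; ++oi) {
            int ii = oi * stride - pad + ki;
            if (ii < 0 || ii >= H) continue;
            xcol[ii] += cc[(std::size_t)(oi + Ho * oj) * cols.n_rows];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xd,
                             NumericVector w, NumericVector b,
                             int k, int stride, int pad) {
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Cout = b.size();
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  arma::mat Wm(const_cast<double*>(w.begin()), (std::size_t)k * k * C, Cout, false);
  NumericVector y((std::size_t)Ho * Wo * Cout * N);
  arma::mat cols((std::size_t)k * k * C, (std::size_t)Ho * Wo);
  std::size_t xs = (std::size_t)H * W * C, ys = (std::size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xs, H, W, C, k, stride, pad, Ho, Wo, cols);
    arma::mat yt(y.begin() + n * ys, (std::size_t)Ho * Wo, Cout, false, true);
    yt = cols.t() * Wm;
    for (int c = 0; c < Cout; ++c) yt.col(c) += b[c];
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector xd,
                    NumericVector w, NumericVector dy, IntegerVector yd,
                    int k, int stride, int pad, bool need_dx) {
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = yd[0], Wo = yd[1], Cout = yd[2];
  arma::mat Wm(const_cast<double*>(w.begin()), (std::size_t)k * k * C, Cout, false);
  NumericVector dw((std::size_t)k * k * C * Cout);
  NumericVector db(Cout);
  NumericVector dx(need_dx ? x.size() : 0);
  arma::mat dWm(dw.begin(), (std::size_t)k * k * C, Cout, false, true);
  arma::mat cols((std::size_t)k * k * C, (std::size_t)Ho * Wo);
  std::size_t xs = (std::size_t)H * W * C, ys = (std::size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    arma::mat dyt(const_cast<double*>(dy.begin()) + n * ys,
                  (std::size_t)Ho * Wo, Cout, false);
    im2col(x.begin() + n * xs, H, W, C, k, stride, pad, Ho, Wo, cols);
    dWm += cols * dyt;
    for (int c = 0; c < Cout; ++c) db[c] += arma::accu(dyt.col(c));
    if (need_dx) {
      arma::mat dcols = Wm * dyt.t();
      col2im(dcols, H, W, C, k, stride, pad, Ho, Wo, dx.begin() + n * xs);
    }
  }
  dw.attr("dim") = IntegerVector::create(k, k, C, Cout);
  if (need_dx) dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector cpp_convt2d_fwd(NumericVector x, IntegerVector xd,
                              NumericVector w, NumericVector b,
                              int k, int stride, int pad) {
  int Hi = xd[0], Wi = xd[1], Cin = xd[2], N = xd[3];
  int Cout = b.size();
  int Ho = (Hi - 1) * stride - 2 * pad + k;
  int Wo = (Wi - 1) * stride - 2 * pad + k;
  if (Ho < 1 || Wo < 1) stop("conv_transpose2d: output size would be empty");
  arma::mat Wm(const_cast<double*>(w.begin()), (std::size_t)k * k * Cout, Cin, false);
  NumericVector y((std::size_t)Ho * Wo * Cout * N);
  std::size_t xs = (std::size_t)Hi * Wi * Cin, ys = (std::size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + n * xs,
                (std::size_t)Hi * Wi, Cin, false);
    arma::mat cols = Wm * X.t();
    col2im(cols, Ho, Wo, Cout, k, stride, pad, Hi, Wi, y.begin() + n * ys);
    arma::mat yt(y.begin() + n * ys, (std::size_t)Ho * Wo, Cout, false, true);
    for (int c = 0; c < Cout; ++c) yt.col(c) += b[c];
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_convt2d_bwd(NumericVector x, IntegerVector xd,
                     NumericVector w, NumericVector dy, IntegerVector yd,
                     int k, int stride, int pad, bool need_dx) {
  int Hi = xd[0], Wi = xd[1], Cin = xd[2], N = xd[3];
  int Ho = yd[0], Wo = yd[1], Cout = yd[2];
  arma::mat Wm(const_cast<double*>(w.begin()), (std::size_t)k * k * Cout, Cin, false);
  NumericVector dw((std::size_t)k * k * Cout * Cin);
  NumericVector db(Cout);
  NumericVector dx(need_dx ? x.size() : 0);
  arma::mat dWm(dw.begin(), (std::size_t)k * k * Cout, Cin, false, true);
  arma::mat cols((std::size_t)k * k * Cout, (std::size_t)Hi * Wi);
  std::size_t xs = (std::size_t)Hi * Wi * Cin, ys = (std::size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    // treat dy as the "input" of the adjoint convolution
    im2col(dy.begin() + n * ys, Ho, Wo, Cout, k, stride, pad, Hi, Wi, cols);
    arma::mat X(const_cast<double*>(x.begin()) + n * xs,
                (std::size_t)Hi * Wi, Cin, false);
    dWm += cols * X;
    arma::mat dyt(const_cast<double*>(dy.begin()) + n * ys,
                  (std::size_t)Ho * Wo, Cout, false);
    for (int c = 0; c < Cout; ++c) db[c] += arma::accu(dyt.col(c));
    if (need_dx) {
      arma::mat dXt(dx.begin() + n * xs, (std::size_t)Hi * Wi, Cin, false, true);
      dXt = cols.t() * Wm;
    }
  }
  dw.attr("dim") = IntegerVector::create(k, k, Cout, Cin);
  if (need_dx) dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
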