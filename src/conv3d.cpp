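// 3x3x3 "same" convolution over a 5-D activation array (X, Y, Z, C, T),
// frames along T treated as a batch. Implemented as im2col + BLAS matrix
// products. Feature ordering inside the im2col block is offset-fastest:
// column index f = o + 27*c with o = (dx+1) + 3*(dy+1) + 9*(dz+1).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col_frame(const double* xt, int X, int Y, int Z, int C) {
  const R_xlen_t V = (R_xlen_t)X * Y * Z;
  arma::mat cols(V, 27 * (R_xlen_t)C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = xt + (R_xlen_t)c * V;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          const int o = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
          double* col = cols.colptr(o + 27 * (R_xlen_t)c);
          for (int k = 0; k < Z; ++k) {
            const int ks = k + dz;
            if (ks < 0 || ks >= Z) continue;
            for (int j = 0; j < Y; ++j) {
              const int js = j + dy;
              if (js < 0 || js >= Y) continue;
              const int i0 = (dx < 0) ? 1 : 0;
              const int i1 = (dx > 0) ? X - 1 : X;
              const double* src = xc + (R_xlen_t)(ks * Y + js) * X + dx;
              double* dst = col + (R_xlen_t)(k * Y + j) * X;
              for (int i = i0; i < i1; ++i) dst[i] = src[i];
            }
          }
        }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, IntegerVector dims,
                             NumericMatrix w, NumericVector b) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3], T = dims[4];
  const R_xlen_t V = (R_xlen_t)X * Y * Z;
  const int Cout = w.ncol();
  if (w.nrow() != 27 * C) stop("weight rows must equal 27 * input channels");
  arma::mat W(w.begin(), w.nrow(), Cout, false);
  arma::colvec bias(b.begin(), Cout, false);
  NumericVector out(V * Cout * (R_xlen_t)T);
  for (int t = 0; t < T; ++t) {
    const double* xt = x.begin() + (R_xlen_t)t * V * C;
    arma::mat cols = im2col_frame(xt, X, Y, Z, C);
    arma::mat yt(out.begin() + (R_xlen_t)t * V * Cout, V, Cout, false, true);
    yt = cols * W;
    yt.each_row() += bias.t();
  }
  out.attr("dim") = IntegerVector::create(X, Y, Z, Cout, T);
  return out;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, IntegerVector dims,
                    NumericMatrix w, NumericVector dy) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3], T = dims[4];
  const R_xlen_t V = (R_xlen_t)X * Y * Z;
  const int Cout = w.ncol();
  arma::mat W(w.begin(), w.nrow(), Cout, false);
  arma::mat dW(27 * (R_xlen_t)C, Cout, arma::fill::zeros);
  arma::colvec db(Cout, arma::fill::zeros);
  NumericVector dx(x.size());
  for (int t = 0; t < T; ++t) {
    const double* xt = x.begin() + (R_xlen_t)t * V * C;
    arma::mat cols = im2col_frame(xt, X, Y, Z, C);
    const arma::mat dyt(const_cast<double*>(dy.begin()) + (R_xlen_t)t * V * Cout,
                        V, Cout, false, true);
    dW += cols.t() * dyt;
    db += arma::sum(dyt, 0).t();
    arma::mat dcols = dyt * W.t();  // V x 27C
    double* dxt = dx.begin() + (R_xlen_t)t * V * C;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxt + (R_xlen_t)c * V;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy_ = -1; dy_ <= 1; ++dy_)
          for (int dx_ = -1; dx_ <= 1; ++dx_) {
            const int o = (dx_ + 1) + 3 * (dy_ + 1) + 9 * (dz + 1);
            const double* col = dcols.colptr(o + 27 * (R_xlen_t)c);
            for (int k = 0; k < Z; ++k) {
              const int ks = k + dz;
              if (ks < 0 || ks >= Z) continue;
              for (int j = 0; j < Y; ++j) {
                const int js = j + dy_;
                if (js < 0 || js >= Y) continue;
                const int i0 = (dx_ < 0) ? 1 : 0;
                const int i1 = (dx_ > 0) ? X - 1 : X;
                double* dst = dxc + (R_xlen_t)(ks * Y + js) * X + dx_;
                const double* src = col + (R_xlen_t)(k * Y + j) * X;
                for (int i = i0; i < i1; ++i) dst[i] += src[i];
              }
            }
          }
    }
  }
  dx.attr("dim") = IntegerVector::create(X, Y, Z, C, T);
  return List::create(_["dx"] = dx,
                      _["dw"] = NumericMatrix(wrap(dW)),
                      _["db"] = NumericVector(wrap(db)));
}

// 2x2x2 average pooling, stride 2, over (X, Y, Z, C, T).
// [[Rcpp::export]]
NumericVector avgpool3d_fwd_cpp(NumericVector x, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3], T = dims[4];
  if (X % 2 || Y % 2 || Z % 2) stop("spatial dims must be even for 2x2x2 pooling");
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  const R_xlen_t V = (R_xlen_t)X * Y * Z, Vo = (R_xlen_t)Xo * Yo * Zo;
  NumericVector out(Vo * C * (R_xlen_t)T);
  for (R_xlen_t ct = 0; ct < (R_xlen_t)C * T; ++ct) {
    const double* xi = x.begin() + ct * V;
    double* yo = out.begin() + ct * Vo;
    for (int k = 0; k < Zo; ++k)
      for (int j = 0; j < Yo; ++j)
        for (int i = 0; i < Xo; ++i) {
          double s = 0;
          for (int kk = 0; kk < 2; ++kk)
            for (int jj = 0; jj < 2; ++jj)
              for (int ii = 0; ii < 2; ++ii)
                s += xi[(R_xlen_t)((2 * k + kk) * Y + 2 * j + jj) * X + 2 * i + ii];
          yo[(R_xlen_t)(k * Yo + j) * Xo + i] = s / 8.0;
        }
  }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C, T);
  return out;
}

// [[Rcpp::export]]
NumericVector avgpool3d_bwd_cpp(NumericVector dy, IntegerVector dims_in) {
  const int X = dims_in[0], Y = dims_in[1], Z = dims_in[2],
            C = dims_in[3], T = dims_in[4];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  const R_xlen_t V = (R_xlen_t)X * Y * Z, Vo = (R_xlen_t)Xo * Yo * Zo;
  NumericVector dx(V * C * (R_xlen_t)T);
  for (R_xlen_t ct = 0; ct < (R_xlen_t)C * T; ++ct) {
    const double* g = dy.begin() + ct * Vo;
    double* d = dx.begin() + ct * V;
    for (int k = 0; k < Zo; ++k)
      for (int j = 0; j < Yo; ++j)
        for (int i = 0; i < Xo; ++i) {
          const double v = g[(R_xlen_t)(k * Yo + j) * Xo + i] / 8.0;
          for (int kk = 0; kk < 2; ++kk)
            for (int jj = 0; jj < 2; ++jj)
              for (int ii = 0; ii < 2; ++ii)
                d[(R_xlen_t)((2 * k + kk) * Y + 2 * j + jj) * X + 2 * i + ii] = v;
        }
  }
  dx.attr("dim") = IntegerVector::create(X, Y, Z, C, T);
  return dx;
}
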