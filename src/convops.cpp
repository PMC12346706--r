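#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Valid (no padding) convolutions over H x W x C arrays, lowered to GEMM via
// im2col / col2im.  Output position index p = j*oh + i (column-major over the
// output grid) so a P x Cout matrix reinterprets directly as an oh x ow x Cout
// array.  Patch index k_idx = c*k*k + kj*k + ki (ki = row offset, kj = col
// offset); weight matrices must be packed in the same order.

static void out_geom(int H, int W, int k, int s, int &oh, int &ow) {
  oh = (H - k) / s + 1;
  ow = (W - k) / s + 1;
}

static mat im2col(const cube &x, int k, int s) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int oh, ow;
  out_geom(H, W, k, s, oh, ow);
  mat cols(oh * (sword)ow, k * k * (sword)C);
  for (int c = 0; c < C; ++c) {
    const mat &xc = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = c * k * k + kj * k + ki;
        double *dst = cols.colptr(col);
        for (int j = 0; j < ow; ++j) {
          const double *src = xc.colptr(j * s + kj) + ki;
          for (int i = 0; i < oh; ++i)
            dst[j * oh + i] = src[i * s];
        }
      }
    }
  }
  return cols;
}

static cube col2im_add(const mat &cols, int H, int W, int C, int k, int s) {
  int oh, ow;
  out_geom(H, W, k, s, oh, ow);
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat &xc = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = c * k * k + kj * k + ki;
        const double *src = cols.colptr(col);
        for (int j = 0; j < ow; ++j) {
          double *dst = xc.colptr(j * s + kj) + ki;
          for (int i = 0; i < oh; ++i)
            dst[i * s] += src[j * oh + i];
        }
      }
    }
  }
  return x;
}

// y(p, co) = sum_k cols(p, k) w(k, co) + b(co)
// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube &x, const arma::mat &w,
                      const arma::vec &b, int k, int s) {
  const int H = x.n_rows, W = x.n_cols;
  int oh, ow;
  out_geom(H, W, k, s, oh, ow);
  if (oh < 1 || ow < 1) Rcpp::stop("input smaller than kernel");
  if ((int)w.n_rows != k * k * (int)x.n_slices)
    Rcpp::stop("weight/kernel geometry mismatch");
  mat y = im2col(x, k, s) * w;
  y.each_row() += b.t();
  return cube(y.memptr(), oh, ow, w.n_cols);
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube &x, const arma::mat &w,
                      const arma::cube &gy, int k, int s,
                      bool need_input, bool need_params) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat gym(const_cast<double *>(gy.memptr()), gy.n_rows * gy.n_cols,
          gy.n_slices, false, true);
  Rcpp::List out;
  if (need_input) {
    mat gcols = gym * w.t();
    out["gx"] = col2im_add(gcols, H, W, C, k, s);
  }
  if (need_params) {
    mat cols = im2col(x, k, s);
    out["gw"] = mat(cols.t() * gym);
    out["gb"] = vec(sum(gym, 0).t());
  }
  return out;
}

// Transposed convolution: x is h x w x Cin, w is Cin x (k*k*Cout),
// output ((h-1)*s + k) square, Cout channels.
// [[Rcpp::export]]
arma::cube convt2d_fwd(const arma::cube &x, const arma::mat &w,
                       const arma::vec &b, int k, int s) {
  const int h = x.n_rows, wd = x.n_cols, Cin = x.n_slices;
  if ((int)w.n_rows != Cin) Rcpp::stop("weight/channel mismatch");
  const int Cout = w.n_cols / (k * k);
  const int H = (h - 1) * s + k, W = (wd - 1) * s + k;
  mat xm(const_cast<double *>(x.memptr()), h * (sword)wd, Cin, false, true);
  mat ycols = xm * w;
  cube y = col2im_add(ycols, H, W, Cout, k, s);
  for (int c = 0; c < Cout; ++c) y.slice(c) += b(c);
  return y;
}

// [[Rcpp::export]]
Rcpp::List convt2d_bwd(const arma::cube &x, const arma::mat &w,
                       const arma::cube &gy, int k, int s,
                       bool need_input, bool need_params) {
  const int h = x.n_rows, wd = x.n_cols, Cin = x.n_slices;
  mat gycols = im2col(gy, k, s); // (h*w) x (k*k*Cout)
  Rcpp::List out;
  if (need_input) {
    mat gxm = gycols * w.t();
    out["gx"] = cube(gxm.memptr(), h, wd, Cin);
  }
  if (need_params) {
    mat xm(const_cast<double *>(x.memptr()), h * (sword)wd, Cin, false, true);
    out["gw"] = mat(xm.t() * gycols);
    const int Cout = w.n_cols / (k * k);
    vec gb(Cout);
    for (int c = 0; c < Cout; ++c) gb(c) = accu(gy.slice(c));
    out["gb"] = gb;
  }
  return out;
}
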