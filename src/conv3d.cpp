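// 3D convolution core: im2col + GEMM (BLAS) with z-chunking so the column
// buffer stays bounded at full MRI scale.
//
// Array layouts follow R column-major order:
//   feature volumes x : (d1, d2, d3, Cin, B)
//   kernels w         : (k, k, k, Cin, Cout), cubic kernels, k in {1, 3}
// Convolution is the CNN cross-correlation convention with equal stride and
// zero-padding on every spatial axis.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_dim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Max doubles in the im2col buffer (~240 MB); one z-chunk never exceeds it.
static const double COLS_BUDGET = 3e7;

static void im2col_chunk(const double* x, int d1, int d2, int d3, int Cin,
                         int k, int s, int p, int o1, int o2,
                         int l0, int nl, arma::mat& cols) {
  cols.zeros();
  const int k3 = k * k * k;
  for (int l = l0; l < l0 + nl; ++l) {
    const int z0 = l * s - p;
    for (int j = 0; j < o2; ++j) {
      const int y0 = j * s - p;
      for (int i = 0; i < o1; ++i) {
        const int x0 = i * s - p;
        double* colptr = cols.colptr(i + (size_t)o1 * j + (size_t)o1 * o2 * (l - l0));
        for (int ci = 0; ci < Cin; ++ci) {
          const double* xc = x + (size_t)ci * d1 * d2 * d3;
          for (int c = 0; c < k; ++c) {
            const int zz = z0 + c;
            if (zz < 0 || zz >= d3) continue;
            for (int b = 0; b < k; ++b) {
              const int yy = y0 + b;
              if (yy < 0 || yy >= d2) continue;
              const double* src = xc + ((size_t)zz * d2 + yy) * d1;
              double* dst = colptr + (size_t)ci * k3 + c * k * k + b * k;
              for (int a = 0; a < k; ++a) {
                const int xx = x0 + a;
                if (xx >= 0 && xx < d1) dst[a] = src[xx];
              }
            }
          }
        }
      }
    }
  }
}

static void col2im_chunk_add(double* dx, int d1, int d2, int d3, int Cin,
                             int k, int s, int p, int o1, int o2,
                             int l0, int nl, const arma::mat& cols) {
  const int k3 = k * k * k;
  for (int l = l0; l < l0 + nl; ++l) {
    const int z0 = l * s - p;
    for (int j = 0; j < o2; ++j) {
      const int y0 = j * s - p;
      for (int i = 0; i < o1; ++i) {
        const int x0 = i * s - p;
        const double* colptr = cols.colptr(i + (size_t)o1 * j + (size_t)o1 * o2 * (l - l0));
        for (int ci = 0; ci < Cin; ++ci) {
          double* xc = dx + (size_t)ci * d1 * d2 * d3;
          for (int c = 0; c < k; ++c) {
            const int zz = z0 + c;
            if (zz < 0 || zz >= d3) continue;
            for (int b = 0; b < k; ++b) {
              const int yy = y0 + b;
              if (yy < 0 || yy >= d2) continue;
              double* dst0 = xc + ((size_t)zz * d2 + yy) * d1;
              const double* src = colptr + (size_t)ci * k3 + c * k * k + b * k;
              for (int a = 0; a < k; ++a) {
                const int xx = x0 + a;
                if (xx >= 0 && xx < d1) dst0[xx] += src[a];
              }
            }
          }
        }
      }
    }
  }
}

static void get_dims(const NumericVector& v, int* d, int n, const char* what) {
  IntegerVector dim = v.attr("dim");
  if (dim.size() != n) stop("%s must be a rank-%d array", what, n);
  for (int i = 0; i < n; ++i) d[i] = dim[i];
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad) {
  int xd[5], wd[5];
  get_dims(x, xd, 5, "x");
  get_dims(w, wd, 5, "w");
  const int d1 = xd[0], d2 = xd[1], d3 = xd[2], Cin = xd[3], B = xd[4];
  const int k = wd[0], Cout = wd[4];
  if (wd[1] != k || wd[2] != k) stop("kernel must be cubic");
  if (wd[3] != Cin) stop("kernel input channels (%d) do not match x (%d)", wd[3], Cin);
  if (k != 1 && k != 3) stop("kernel spatial size must be 1 or 3");
  const int o1 = out_dim(d1, k, stride, pad);
  const int o2 = out_dim(d2, k, stride, pad);
  const int o3 = out_dim(d3, k, stride, pad);
  if (o1 < 1 || o2 < 1 || o3 < 1) stop("input too small for this kernel/stride/pad");

  const int k3 = k * k * k;
  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k3 * Cin, Cout, false, true);
  arma::vec bvec;
  bool has_bias = bias.isNotNull();
  if (has_bias) {
    NumericVector bb(bias);
    if ((int)bb.size() != Cout) stop("bias length must equal output channels");
    bvec = arma::vec(bb.begin(), Cout);
  }

  NumericVector y((size_t)o1 * o2 * o3 * Cout * B);
  y.attr("dim") = IntegerVector::create(o1, o2, o3, Cout, B);

  int nl = (int)std::max(1.0, COLS_BUDGET / ((double)k3 * Cin * o1 * o2));
  if (nl > o3) nl = o3;
  arma::mat cols((size_t)k3 * Cin, (size_t)o1 * o2 * nl);

  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + (size_t)b * d1 * d2 * d3 * Cin;
    double* yb = y.begin() + (size_t)b * o1 * o2 * o3 * Cout;
    for (int l0 = 0; l0 < o3; l0 += nl) {
      const int cl = std::min(nl, o3 - l0);
      arma::mat cview = cols.cols(0, (size_t)o1 * o2 * cl - 1);
      im2col_chunk(xb, d1, d2, d3, Cin, k, stride, pad, o1, o2, l0, cl, cview);
      arma::mat Y = cview.t() * Wm;  // (Npos x Cout)
      if (has_bias) Y.each_row() += bvec.t();
      for (int co = 0; co < Cout; ++co) {
        std::memcpy(yb + (size_t)co * o1 * o2 * o3 + (size_t)o1 * o2 * l0,
                    Y.colptr(co), sizeof(double) * (size_t)o1 * o2 * cl);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  int xd[5], wd[5], yd[5];
  get_dims(x, xd, 5, "x");
  get_dims(w, wd, 5, "w");
  get_dims(dy, yd, 5, "dy");
  const int d1 = xd[0], d2 = xd[1], d3 = xd[2], Cin = xd[3], B = xd[4];
  const int k = wd[0], Cout = wd[4];
  const int o1 = yd[0], o2 = yd[1], o3 = yd[2];
  if (yd[3] != Cout || yd[4] != B) stop("dy shape inconsistent with x/w");
  if (o1 != out_dim(d1, k, stride, pad) || o2 != out_dim(d2, k, stride, pad) ||
      o3 != out_dim(d3, k, stride, pad))
    stop("dy spatial shape inconsistent with x/w/stride/pad");

  const int k3 = k * k * k;
  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k3 * Cin, Cout, false, true);

  NumericVector dx((size_t)d1 * d2 * d3 * Cin * B);
  dx.attr("dim") = IntegerVector::create(d1, d2, d3, Cin, B);
  NumericVector dw((size_t)k3 * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(k, k, k, Cin, Cout);
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), (size_t)k3 * Cin, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);

  int nl = (int)std::max(1.0, COLS_BUDGET / ((double)k3 * Cin * o1 * o2));
  if (nl > o3) nl = o3;
  arma::mat cols((size_t)k3 * Cin, (size_t)o1 * o2 * nl);

  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + (size_t)b * d1 * d2 * d3 * Cin;
    const double* dyb = dy.begin() + (size_t)b * o1 * o2 * o3 * Cout;
    double* dxb = dx.begin() + (size_t)b * d1 * d2 * d3 * Cin;
    for (int l0 = 0; l0 < o3; l0 += nl) {
      const int cl = std::min(nl, o3 - l0);
      const size_t Np = (size_t)o1 * o2 * cl;
      arma::mat cview = cols.cols(0, Np - 1);
      im2col_chunk(xb, d1, d2, d3, Cin, k, stride, pad, o1, o2, l0, cl, cview);
      arma::mat dYm(Np, Cout);
      for (int co = 0; co < Cout; ++co) {
        std::memcpy(dYm.colptr(co),
                    dyb + (size_t)co * o1 * o2 * o3 + (size_t)o1 * o2 * l0,
                    sizeof(double) * Np);
      }
      dWm += cview * dYm;
      dbv += arma::sum(dYm, 0).t();
      arma::mat dcols = Wm * dYm.t();  // (k3*Cin x Np)
      col2im_chunk_add(dxb, d1, d2, d3, Cin, k, stride, pad, o1, o2, l0, cl, dcols);
    }
  }
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}
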