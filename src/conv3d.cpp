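// 3D convolution and max-pooling kernels for volumetric CNNs.
// Layout convention (column-major, as R stores arrays):
//   activations x: [d1, d2, d3, channels, batch]
//   weights    w: [k, k, k, c_in, c_out]   (cubic kernels only)
// Convolution is implemented as im2col + BLAS gemm via Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int d, int k, int s, int p) {
  return (d + 2 * p - k) / s + 1;
}

// Fill `col` ((k^3*cin) x (o1*o2*o3)) from one sample slab of x.
// Row index r = dx + k*dy + k^2*dz + k^3*c; padded positions are zero.
static void im2col3d(const double* x, int d1, int d2, int d3, int cin,
                     int k, int s, int p, int o1, int o2, int o3,
                     arma::mat& col) {
  col.zeros();
  const int sp = d1 * d2 * d3;
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + (size_t)c * sp;
    for (int dz = 0; dz < k; ++dz)
      for (int dy = 0; dy < k; ++dy)
        for (int dx = 0; dx < k; ++dx) {
          const int r = dx + k * (dy + k * (dz + k * c));
          for (int oz = 0; oz < o3; ++oz) {
            const int iz = oz * s - p + dz;
            if (iz < 0 || iz >= d3) continue;
            for (int oy = 0; oy < o2; ++oy) {
              const int iy = oy * s - p + dy;
              if (iy < 0 || iy >= d2) continue;
              const size_t obase = (size_t)o1 * (oy + (size_t)o2 * oz);
              const size_t ibase = (size_t)d1 * (iy + (size_t)d2 * iz);
              for (int ox = 0; ox < o1; ++ox) {
                const int ix = ox * s - p + dx;
                if (ix < 0 || ix >= d1) continue;
                col(r, obase + ox) = xc[ibase + ix];
              }
            }
          }
        }
  }
}

// Scatter-accumulate of col2im: inverse of im2col3d.
static void col2im3d(const arma::mat& col, int d1, int d2, int d3, int cin,
                     int k, int s, int p, int o1, int o2, int o3,
                     double* dx_out) {
  const int sp = d1 * d2 * d3;
  for (int c = 0; c < cin; ++c) {
    double* xc = dx_out + (size_t)c * sp;
    for (int dz = 0; dz < k; ++dz)
      for (int dy = 0; dy < k; ++dy)
        for (int dxk = 0; dxk < k; ++dxk) {
          const int r = dxk + k * (dy + k * (dz + k * c));
          for (int oz = 0; oz < o3; ++oz) {
            const int iz = oz * s - p + dz;
            if (iz < 0 || iz >= d3) continue;
            for (int oy = 0; oy < o2; ++oy) {
              const int iy = oy * s - p + dy;
              if (iy < 0 || iy >= d2) continue;
              const size_t obase = (size_t)o1 * (oy + (size_t)o2 * oz);
              const size_t ibase = (size_t)d1 * (iy + (size_t)d2 * iz);
              for (int ox = 0; ox < o1; ++ox) {
                const int ix = ox * s - p + dxk;
                if (ix < 0 || ix >= d1) continue;
                xc[ibase + ix] += col(r, obase + ox);
              }
            }
          }
        }
  }
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w,
                         Nullable<NumericVector> bias,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int d1 = xd[0], d2 = xd[1], d3 = xd[2], cin = xd[3], n = xd[4];
  const int k = wd[0], cout = wd[4];
  if (wd[3] != cin) stop("channel mismatch between input and weights");
  const int o1 = out_dim(d1, k, stride, pad), o2 = out_dim(d2, k, stride, pad),
            o3 = out_dim(d3, k, stride, pad);
  if (o1 < 1 || o2 < 1 || o3 < 1) stop("kernel larger than (padded) input");
  const size_t ovox = (size_t)o1 * o2 * o3, ispan = (size_t)d1 * d2 * d3 * cin;

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * k * cin, cout,
               false, true);
  NumericVector y((size_t)ovox * cout * n);
  y.attr("dim") = IntegerVector::create(o1, o2, o3, cout, n);

  arma::mat col((size_t)k * k * k * cin, ovox);
  arma::rowvec bv;
  const bool has_b = bias.isNotNull();
  if (has_b) bv = arma::rowvec(NumericVector(bias).begin(), cout);

  for (int i = 0; i < n; ++i) {
    im2col3d(x.begin() + (size_t)i * ispan, d1, d2, d3, cin, k, stride, pad,
             o1, o2, o3, col);
    arma::mat Yt(y.begin() + (size_t)i * ovox * cout, ovox, cout, false, true);
    Yt = col.t() * Wm;
    if (has_b) Yt.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad, bool need_dx, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int d1 = xd[0], d2 = xd[1], d3 = xd[2], cin = xd[3], n = xd[4];
  const int k = wd[0], cout = wd[4];
  const int o1 = yd[0], o2 = yd[1], o3 = yd[2];
  const size_t ovox = (size_t)o1 * o2 * o3, ispan = (size_t)d1 * d2 * d3 * cin;

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * k * cin, cout,
               false, true);
  arma::mat dW((size_t)k * k * k * cin, cout, arma::fill::zeros);
  arma::rowvec db(cout, arma::fill::zeros);

  NumericVector dx;
  if (need_dx) {
    dx = NumericVector(x.size());
    dx.attr("dim") = xd;
  }
  arma::mat col((size_t)k * k * k * cin, ovox);

  for (int i = 0; i < n; ++i) {
    im2col3d(x.begin() + (size_t)i * ispan, d1, d2, d3, cin, k, stride, pad,
             o1, o2, o3, col);
    arma::mat dYt(const_cast<double*>(dy.begin()) + (size_t)i * ovox * cout,
                  ovox, cout, false, true);
    dW += col * dYt;
    if (has_bias) db += arma::sum(dYt, 0);
    if (need_dx) {
      arma::mat dcol = Wm * dYt.t();
      col2im3d(dcol, d1, d2, d3, cin, k, stride, pad, o1, o2, o3,
               dx.begin() + (size_t)i * ispan);
    }
  }
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = wd;
  List out = List::create(_["dW"] = dWr,
                          _["db"] = has_bias
                              ? (SEXP)NumericVector(db.begin(), db.end())
                              : (SEXP)R_NilValue,
                          _["dx"] = need_dx ? (SEXP)dx : (SEXP)R_NilValue);
  return out;
}

// [[Rcpp::export(name = ".maxpool3d_fwd")]]
List maxpool3d_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int d1 = xd[0], d2 = xd[1], d3 = xd[2], cn = xd[3] * xd[4];
  const int o1 = out_dim(d1, k, stride, pad), o2 = out_dim(d2, k, stride, pad),
            o3 = out_dim(d3, k, stride, pad);
  if (o1 < 1 || o2 < 1 || o3 < 1) stop("pooling window larger than input");
  const size_t sp = (size_t)d1 * d2 * d3, osp = (size_t)o1 * o2 * o3;

  NumericVector y(osp * cn);
  IntegerVector idx(osp * cn);  // 0-based spatial argmax within the slab
  y.attr("dim") = IntegerVector::create(o1, o2, o3, xd[3], xd[4]);

  for (int c = 0; c < cn; ++c) {
    const double* xs = x.begin() + (size_t)c * sp;
    double* ys = y.begin() + (size_t)c * osp;
    int* is = idx.begin() + (size_t)c * osp;
    for (int oz = 0; oz < o3; ++oz)
      for (int oy = 0; oy < o2; ++oy)
        for (int ox = 0; ox < o1; ++ox) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int dz = 0; dz < k; ++dz) {
            const int iz = oz * stride - pad + dz;
            if (iz < 0 || iz >= d3) continue;
            for (int dy = 0; dy < k; ++dy) {
              const int iy = oy * stride - pad + dy;
              if (iy < 0 || iy >= d2) continue;
              for (int dx = 0; dx < k; ++dx) {
                const int ix = ox * stride - pad + dx;
                if (ix < 0 || ix >= d1) continue;
                const size_t ii = ix + (size_t)d1 * (iy + (size_t)d2 * iz);
                if (xs[ii] > best) { best = xs[ii]; besti = ii; }
              }
            }
          }
          const size_t oi = ox + (size_t)o1 * (oy + (size_t)o2 * oz);
          ys[oi] = best;
          is[oi] = (int)besti;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool3d_bwd")]]
NumericVector maxpool3d_bwd(NumericVector dy, IntegerVector idx,
                            IntegerVector xdim) {
  const size_t sp = (size_t)xdim[0] * xdim[1] * xdim[2];
  const int cn = xdim[3] * xdim[4];
  const size_t osp = (size_t)dy.size() / cn;
  NumericVector dx(sp * cn);
  dx.attr("dim") = xdim;
  for (int c = 0; c < cn; ++c) {
    const double* ds = dy.begin() + (size_t)c * osp;
    const int* is = idx.begin() + (size_t)c * osp;
    double* xs = dx.begin() + (size_t)c * sp;
    for (size_t i = 0; i < osp; ++i) xs[(size_t)is[i]] += ds[i];
  }
  return dx;
}
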