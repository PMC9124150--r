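// Compiled kernels for the segmentation engine: same-padded dilated
// convolutions via im2col + GEMM, max pooling, linear/nearest grid
// resampling with exact transpose gradients, and surface-distance search.
// Arrays are channel-first (C, X, Y, Z) in R's column-major layout, so a
// (Cout x N) GEMM result maps straight back onto an output array.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_extent(int in, int k, int s, int d, int pad) {
  return (in + 2 * pad - ((k - 1) * d + 1)) / s + 1;
}

// Reusable workspace: repeated large allocations would be returned to the
// OS between calls and re-faulted in, which dominates at this problem size.
static arma::mat& work_col() { static arma::mat m; return m; }
static arma::mat& work_gcol() { static arma::mat m; return m; }

// Gather patches: col is (C*kvol) x N. Row index r = c + C*kidx,
// kidx = a + k1*(b + k2*cc). Zero padding outside bounds; only columns
// whose patch touches the boundary are pre-zeroed.
static void im2col(const double* x, int C, const int in[3], const int out[3],
                   const int k[3], const int s[3], const int d[3],
                   const int pad[3], arma::mat& col) {
  const int kvol = k[0] * k[1] * k[2];
  const arma::uword N = (arma::uword)out[0] * out[1] * out[2];
  if (col.n_rows != (arma::uword)(C * kvol) || col.n_cols != N) {
    col.set_size(C * kvol, N);
  }
  const int reach[3] = {(k[0] - 1) * d[0], (k[1] - 1) * d[1],
                        (k[2] - 1) * d[2]};
  arma::uword n = 0;
  for (int oz = 0; oz < out[2]; ++oz) {
    const int z0 = oz * s[2] - pad[2];
    const bool zin = z0 >= 0 && z0 + reach[2] < in[2];
    for (int oy = 0; oy < out[1]; ++oy) {
      const int y0 = oy * s[1] - pad[1];
      const bool yin = zin && y0 >= 0 && y0 + reach[1] < in[1];
      for (int ox = 0; ox < out[0]; ++ox, ++n) {
        const int x0 = ox * s[0] - pad[0];
        double* cp = col.colptr(n);
        const bool interior = yin && x0 >= 0 && x0 + reach[0] < in[0];
        if (!interior) std::fill(cp, cp + (size_t)C * kvol, 0.0);
        int kidx = 0;
        for (int cc = 0; cc < k[2]; ++cc) {
          const int iz = z0 + cc * d[2];
          for (int b = 0; b < k[1]; ++b) {
            const int iy = y0 + b * d[1];
            for (int a = 0; a < k[0]; ++a, ++kidx) {
              const int ix = x0 + a * d[0];
              if (interior || (ix >= 0 && ix < in[0] && iy >= 0 &&
                               iy < in[1] && iz >= 0 && iz < in[2])) {
                const double* src =
                    x + (size_t)C * (ix + (size_t)in[0] * (iy + (size_t)in[1] * iz));
                std::copy(src, src + C, cp + (size_t)C * kidx);
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add transpose of im2col.
static void col2im(const arma::mat& col, double* x, int C, const int in[3],
                   const int out[3], const int k[3], const int s[3],
                   const int d[3], const int pad[3]) {
  arma::uword n = 0;
  for (int oz = 0; oz < out[2]; ++oz) {
    for (int oy = 0; oy < out[1]; ++oy) {
      for (int ox = 0; ox < out[0]; ++ox, ++n) {
        const double* cp = col.colptr(n);
        int kidx = 0;
        for (int cc = 0; cc < k[2]; ++cc) {
          const int iz = oz * s[2] - pad[2] + cc * d[2];
          for (int b = 0; b < k[1]; ++b) {
            const int iy = oy * s[1] - pad[1] + b * d[1];
            for (int a = 0; a < k[0]; ++a, ++kidx) {
              const int ix = ox * s[0] - pad[0] + a * d[0];
              if (ix >= 0 && ix < in[0] && iy >= 0 && iy < in[1] &&
                  iz >= 0 && iz < in[2]) {
                double* dst =
                    x + (size_t)C * (ix + (size_t)in[0] * (iy + (size_t)in[1] * iz));
                const double* src = cp + (size_t)C * kidx;
                for (int c = 0; c < C; ++c) dst[c] += src[c];
              }
            }
          }
        }
      }
    }
  }
}

static void conv_geom(const IntegerVector& xdim, const IntegerVector& ksize,
                      const IntegerVector& stride, const IntegerVector& dilation,
                      int in[3], int k[3], int s[3], int d[3], int pad[3],
                      int out[3]) {
  for (int i = 0; i < 3; ++i) {
    in[i] = xdim[i + 1];
    k[i] = ksize[i];
    s[i] = stride[i];
    d[i] = dilation[i];
    pad[i] = ((k[i] - 1) * d[i]) / 2;
    out[i] = out_extent(in[i], k[i], s[i], d[i], pad[i]);
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_forward(NumericVector x, IntegerVector xdim,
                               NumericVector w, int cout, NumericVector bias,
                               IntegerVector ksize, IntegerVector stride,
                               IntegerVector dilation) {
  const int C = xdim[0];
  int in[3], k[3], s[3], d[3], pad[3], out[3];
  conv_geom(xdim, ksize, stride, dilation, in, k, s, d, pad, out);
  const int K = C * k[0] * k[1] * k[2];
  arma::mat& col = work_col();
  im2col(REAL(x), C, in, out, k, s, d, pad, col);
  arma::mat W(const_cast<double*>(REAL(w)), cout, K, false, true);
  arma::mat Y = W * col;
  Y.each_col() += arma::vec(const_cast<double*>(REAL(bias)), cout, false, true);
  NumericVector res(Y.begin(), Y.end());
  res.attr("dim") = IntegerVector::create(cout, out[0], out[1], out[2]);
  return res;
}

// [[Rcpp::export]]
List cpp_conv_backward(NumericVector x, IntegerVector xdim, NumericVector w,
                       int cout, IntegerVector ksize, IntegerVector stride,
                       IntegerVector dilation, NumericVector gout,
                       bool need_gx) {
  const int C = xdim[0];
  int in[3], k[3], s[3], d[3], pad[3], out[3];
  conv_geom(xdim, ksize, stride, dilation, in, k, s, d, pad, out);
  const int K = C * k[0] * k[1] * k[2];
  const arma::uword N = (arma::uword)out[0] * out[1] * out[2];
  arma::mat& col = work_col();
  im2col(REAL(x), C, in, out, k, s, d, pad, col);
  arma::mat G(const_cast<double*>(REAL(gout)), cout, N, false, true);
  arma::mat W(const_cast<double*>(REAL(w)), cout, K, false, true);
  arma::mat GW = G * col.t();
  arma::vec GB = arma::sum(G, 1);
  NumericVector gwv(GW.begin(), GW.end());
  gwv.attr("dim") = w.attr("dim");
  if (!need_gx) {
    return List::create(_["gx"] = R_NilValue, _["gw"] = gwv,
                        _["gb"] = NumericVector(GB.begin(), GB.end()));
  }
  arma::mat& GCOL = work_gcol();
  if (GCOL.n_rows != (arma::uword)K || GCOL.n_cols != N) GCOL.set_size(K, N);
  GCOL = W.t() * G;
  NumericVector gx(x.size());
  std::fill(gx.begin(), gx.end(), 0.0);
  col2im(GCOL, REAL(gx), C, in, out, k, s, d, pad);
  gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(GB.begin(), GB.end()));
}

// Max pooling with window = stride = pool (extent must divide evenly).
// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, IntegerVector xdim,
                         IntegerVector pool) {
  const int C = xdim[0];
  const int in[3] = {xdim[1], xdim[2], xdim[3]};
  const int p[3] = {pool[0], pool[1], pool[2]};
  const int out[3] = {in[0] / p[0], in[1] / p[1], in[2] / p[2]};
  const size_t nout = (size_t)C * out[0] * out[1] * out[2];
  NumericVector y(nout);
  IntegerVector arg(nout);
  const double* xp = REAL(x);
  size_t n = 0;
  for (int oz = 0; oz < out[2]; ++oz)
    for (int oy = 0; oy < out[1]; ++oy)
      for (int ox = 0; ox < out[0]; ++ox)
        for (int c = 0; c < C; ++c, ++n) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int cc = 0; cc < p[2]; ++cc)
            for (int b = 0; b < p[1]; ++b)
              for (int a = 0; a < p[0]; ++a) {
                const size_t ix = ox * p[0] + a, iy = oy * p[1] + b,
                             iz = oz * p[2] + cc;
                const size_t off =
                    c + (size_t)C * (ix + (size_t)in[0] * (iy + (size_t)in[1] * iz));
                if (xp[off] > best) { best = xp[off]; besti = off; }
              }
          y[n] = best;
          arg[n] = (int)besti;
        }
  y.attr("dim") = IntegerVector::create(C, out[0], out[1], out[2]);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector gout, IntegerVector argmax,
                                   IntegerVector xdim) {
  size_t nin = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(nin);
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[argmax[i]] += gout[i];
  gx.attr("dim") = xdim;
  return gx;
}

struct LinW { int lo, hi; double wlo, whi; };

// Half-pixel-center coordinate mapping, clamped to the grid.
static std::vector<LinW> axis_weights(int in, int out) {
  std::vector<LinW> w(out);
  const double r = (double)in / out;
  for (int o = 0; o < out; ++o) {
    double c = (o + 0.5) * r - 0.5;
    if (c < 0) c = 0;
    if (c > in - 1) c = in - 1;
    int lo = (int)std::floor(c);
    int hi = std::min(lo + 1, in - 1);
    double f = c - lo;
    w[o] = {lo, hi, 1.0 - f, f};
  }
  return w;
}

// [[Rcpp::export]]
NumericVector cpp_resample_linear(NumericVector x, IntegerVector xdim,
                                  IntegerVector oshape) {
  const int C = xdim[0];
  const int in[3] = {xdim[1], xdim[2], xdim[3]};
  const int out[3] = {oshape[0], oshape[1], oshape[2]};
  std::vector<LinW> wx = axis_weights(in[0], out[0]),
                    wy = axis_weights(in[1], out[1]),
                    wz = axis_weights(in[2], out[2]);
  NumericVector y((size_t)C * out[0] * out[1] * out[2]);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  size_t n = 0;
  for (int oz = 0; oz < out[2]; ++oz)
    for (int oy = 0; oy < out[1]; ++oy)
      for (int ox = 0; ox < out[0]; ++ox) {
        const LinW &ax = wx[ox], &ay = wy[oy], &az = wz[oz];
        const int xs[2] = {ax.lo, ax.hi}, ys[2] = {ay.lo, ay.hi},
                  zs[2] = {az.lo, az.hi};
        const double xw[2] = {ax.wlo, ax.whi}, yw[2] = {ay.wlo, ay.whi},
                     zw[2] = {az.wlo, az.whi};
        for (int c = 0; c < C; ++c, ++n) {
          double acc = 0;
          for (int k = 0; k < 2; ++k)
            for (int j = 0; j < 2; ++j)
              for (int i = 0; i < 2; ++i) {
                double wgt = xw[i] * yw[j] * zw[k];
                if (wgt == 0) continue;
                acc += wgt * xp[c + (size_t)C * (xs[i] +
                         (size_t)in[0] * (ys[j] + (size_t)in[1] * zs[k]))];
              }
          yp[n] = acc;
        }
      }
  y.attr("dim") = IntegerVector::create(C, out[0], out[1], out[2]);
  return y;
}

// Exact transpose of cpp_resample_linear.
// [[Rcpp::export]]
NumericVector cpp_resample_linear_grad(NumericVector gout, IntegerVector xdim,
                                       IntegerVector oshape) {
  const int C = xdim[0];
  const int in[3] = {xdim[1], xdim[2], xdim[3]};
  const int out[3] = {oshape[0], oshape[1], oshape[2]};
  std::vector<LinW> wx = axis_weights(in[0], out[0]),
                    wy = axis_weights(in[1], out[1]),
                    wz = axis_weights(in[2], out[2]);
  NumericVector gx((size_t)C * in[0] * in[1] * in[2]);
  std::fill(gx.begin(), gx.end(), 0.0);
  const double* gp = REAL(gout);
  double* xp = REAL(gx);
  size_t n = 0;
  for (int oz = 0; oz < out[2]; ++oz)
    for (int oy = 0; oy < out[1]; ++oy)
      for (int ox = 0; ox < out[0]; ++ox) {
        const LinW &ax = wx[ox], &ay = wy[oy], &az = wz[oz];
        const int xs[2] = {ax.lo, ax.hi}, ys[2] = {ay.lo, ay.hi},
                  zs[2] = {az.lo, az.hi};
        const double xw[2] = {ax.wlo, ax.whi}, yw[2] = {ay.wlo, ay.whi},
                     zw[2] = {az.wlo, az.whi};
        for (int c = 0; c < C; ++c, ++n) {
          const double g = gp[n];
          if (g == 0) continue;
          for (int k = 0; k < 2; ++k)
            for (int j = 0; j < 2; ++j)
              for (int i = 0; i < 2; ++i) {
                double wgt = xw[i] * yw[j] * zw[k];
                if (wgt == 0) continue;
                xp[c + (size_t)C * (xs[i] +
                    (size_t)in[0] * (ys[j] + (size_t)in[1] * zs[k]))] += wgt * g;
              }
        }
      }
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_resample_nearest(NumericVector x, IntegerVector xdim,
                                   IntegerVector oshape) {
  const int C = xdim[0];
  const int in[3] = {xdim[1], xdim[2], xdim[3]};
  const int out[3] = {oshape[0], oshape[1], oshape[2]};
  std::vector<std::vector<int>> idx(3);
  for (int ax = 0; ax < 3; ++ax) {
    idx[ax].resize(out[ax]);
    const double r = (double)in[ax] / out[ax];
    for (int o = 0; o < out[ax]; ++o) {
      int i = (int)std::floor((o + 0.5) * r);
      if (i < 0) i = 0;
      if (i > in[ax] - 1) i = in[ax] - 1;
      idx[ax][o] = i;
    }
  }
  NumericVector y((size_t)C * out[0] * out[1] * out[2]);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  size_t n = 0;
  for (int oz = 0; oz < out[2]; ++oz)
    for (int oy = 0; oy < out[1]; ++oy)
      for (int ox = 0; ox < out[0]; ++ox) {
        const double* src = xp + (size_t)C * (idx[0][ox] +
            (size_t)in[0] * (idx[1][oy] + (size_t)in[1] * idx[2][oz]));
        for (int c = 0; c < C; ++c, ++n) yp[n] = src[c];
      }
  y.attr("dim") = IntegerVector::create(C, out[0], out[1], out[2]);
  return y;
}

// For each row of a (n x 3, physical mm), the minimum Euclidean distance to
// any row of b (m x 3).
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
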