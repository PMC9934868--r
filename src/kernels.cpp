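// Hot numeric kernels: im2col/col2im gathers for the 3x3x3 convolutions and
// trilinear resampling for the elastic augmentation. Everything else runs on
// BLAS through plain R matrix algebra.

#include <Rcpp.h>
using namespace Rcpp;

// Xp: zero-padded array (d1+2, d2+2, d3+2, C) as a flat vector.
// Returns col matrix (d1*d2*d3) x (27*C); column order offset-major,
// channel-minor: column (k-1)*C + ch for offset k, channel ch.
// [[Rcpp::export]]
NumericMatrix cpp_im2col3(NumericVector Xp, IntegerVector d) {
  const int d1 = d[0], d2 = d[1], d3 = d[2], C = d[3];
  const int p1 = d1 + 2, p2 = d2 + 2, p3 = d3 + 2;
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  const R_xlen_t sp = (R_xlen_t)p1 * p2 * p3;
  NumericMatrix col(n, 27 * C);
  const double *xp = Xp.begin();
  int k = 0;
  for (int ox = 0; ox < 3; ++ox) for (int oy = 0; oy < 3; ++oy) for (int oz = 0; oz < 3; ++oz) {
    for (int ch = 0; ch < C; ++ch) {
      double *out = &col(0, k * C + ch);
      const double *src = xp + (R_xlen_t)ch * sp;
      R_xlen_t r = 0;
      for (int x = 0; x < d3; ++x) {
        for (int y = 0; y < d2; ++y) {
          const double *row = src + (R_xlen_t)(x + ox) * p1 * p2 + (R_xlen_t)(y + oy) * p1 + oz;
          for (int z = 0; z < d1; ++z) out[r++] = row[z];
        }
      }
    }
    ++k;
  }
  return col;
}

// Scatter-add the col-space gradient back onto the padded grid.
// [[Rcpp::export]]
NumericVector cpp_col2im3(NumericMatrix dcol, IntegerVector d) {
  const int d1 = d[0], d2 = d[1], d3 = d[2], C = d[3];
  const int p1 = d1 + 2, p2 = d2 + 2, p3 = d3 + 2;
  const R_xlen_t sp = (R_xlen_t)p1 * p2 * p3;
  NumericVector dXp((R_xlen_t)sp * C);
  double *out0 = dXp.begin();
  int k = 0;
  for (int ox = 0; ox < 3; ++ox) for (int oy = 0; oy < 3; ++oy) for (int oz = 0; oz < 3; ++oz) {
    for (int ch = 0; ch < C; ++ch) {
      const double *g = &dcol(0, k * C + ch);
      double *dst = out0 + (R_xlen_t)ch * sp;
      R_xlen_t r = 0;
      for (int x = 0; x < d3; ++x) {
        for (int y = 0; y < d2; ++y) {
          double *row = dst + (R_xlen_t)(x + ox) * p1 * p2 + (R_xlen_t)(y + oy) * p1 + oz;
          for (int z = 0; z < d1; ++z) row[z] += g[r++];
        }
      }
    }
    ++k;
  }
  return dXp;
}

// Trilinear sampling of a 3D array at fractional (z, y, x), clamped to the
// valid domain. Coordinates are 1-based like R indices.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector a, IntegerVector d,
                            NumericVector z, NumericVector y, NumericVector x) {
  const int d1 = d[0], d2 = d[1], d3 = d[2];
  const R_xlen_t n = z.size();
  NumericVector out(n);
  const double *A = a.begin();
  const R_xlen_t s1 = d1, s2 = (R_xlen_t)d1 * d2;
  for (R_xlen_t i = 0; i < n; ++i) {
    double zz = z[i], yy = y[i], xx = x[i];
    if (zz < 1) zz = 1; if (zz > d1) zz = d1;
    if (yy < 1) yy = 1; if (yy > d2) yy = d2;
    if (xx < 1) xx = 1; if (xx > d3) xx = d3;
    int z0 = (int)zz; if (z0 > d1 - 1) z0 = d1 - 1;
    int y0 = (int)yy; if (y0 > d2 - 1) y0 = d2 - 1;
    int x0 = (int)xx; if (x0 > d3 - 1) x0 = d3 - 1;
    double fz = zz - z0, fy = yy - y0, fx = xx - x0;
    const double *p = A + (z0 - 1) + (R_xlen_t)(y0 - 1) * s1 + (R_xlen_t)(x0 - 1) * s2;
    double v000 = p[0], v100 = p[1];
    double v010 = p[s1], v110 = p[s1 + 1];
    double v001 = p[s2], v101 = p[s2 + 1];
    double v011 = p[s1 + s2], v111 = p[s1 + s2 + 1];
    out[i] =
      (1 - fz) * ((1 - fy) * ((1 - fx) * v000 + fx * v001) + fy * ((1 - fx) * v010 + fx * v011)) +
           fz  * ((1 - fy) * ((1 - fx) * v100 + fx * v101) + fy * ((1 - fx) * v110 + fx * v111));
  }
  return out;
}

// Row-wise partial selection of the k smallest entries of a squared
// distance matrix (diagonal excluded); returns n x k 1-based indices.
// [[Rcpp::export]]
IntegerMatrix cpp_row_kmin(NumericMatrix D, int k) {
  const int n = D.nrow();
  IntegerMatrix idx(n, k);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) ord[j] = j;
    std::partial_sort(ord.begin(), ord.begin() + k + 1, ord.end(),
                      [&](int a, int b) {
                        double da = D(i, a), db = D(i, b);
                        if (da != db) return da < db;
                        return a < b;
                      });
    int c = 0;
    for (int j = 0; j <= k && c < k; ++j) {
      if (ord[j] == i) continue;
      idx(i, c++) = ord[j] + 1;
    }
  }
  return idx;
}
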