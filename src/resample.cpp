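#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Resample a 3D volume through an affine index map.
// M is the 4x4 matrix sending 0-based target voxel indices (i,j,k,1) to
// continuous 0-based source indices. Out-of-field voxels receive `fill`.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector src, IntegerVector sdim,
                                  NumericMatrix M, IntegerVector tdim,
                                  bool nearest, double fill) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  NumericVector out((R_xlen_t)tx * ty * tz, fill);
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  R_xlen_t o = 0;
  for (int k = 0; k < tz; ++k) {
    for (int j = 0; j < ty; ++j) {
      double xb = m01 * j + m02 * k + m03;
      double yb = m11 * j + m12 * k + m13;
      double zb = m21 * j + m22 * k + m23;
      for (int i = 0; i < tx; ++i, ++o) {
        double x = m00 * i + xb, y = m10 * i + yb, z = m20 * i + zb;
        if (nearest) {
          int xi = (int)std::lround(x), yi = (int)std::lround(y),
              zi = (int)std::lround(z);
          if (xi < 0 || xi >= sx || yi < 0 || yi >= sy || zi < 0 || zi >= sz)
            continue;
          out[o] = src[xi + (R_xlen_t)sx * (yi + (R_xlen_t)sy * zi)];
        } else {
          if (x < 0 || x > sx - 1 || y < 0 || y > sy - 1 ||
              z < 0 || z > sz - 1)
            continue;
          int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
              z0 = (int)std::floor(z);
          if (x0 > sx - 2) x0 = sx - 2;
          if (y0 > sy - 2) y0 = sy - 2;
          if (z0 > sz - 2) z0 = sz - 2;
          double fx = x - x0, fy = y - y0, fz = z - z0;
          R_xlen_t b = x0 + (R_xlen_t)sx * (y0 + (R_xlen_t)sy * z0);
          R_xlen_t dz = (R_xlen_t)sx * sy;
          double c00 = src[b] * (1 - fx) + src[b + 1] * fx;
          double c10 = src[b + sx] * (1 - fx) + src[b + sx + 1] * fx;
          double c01 = src[b + dz] * (1 - fx) + src[b + dz + 1] * fx;
          double c11 = src[b + dz + sx] * (1 - fx) + src[b + dz + sx + 1] * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          out[o] = c0 * (1 - fz) + c1 * fz;
        }
      }
    }
  }
  return out;
}

// Correlation ratio of the trilinearly sampled moving image conditioned on
// precomputed fixed-image intensity bins (-1 marks voxels to ignore).
// Returns eta^2 in [0,1]; larger is better alignment. NA if the field-of-view
// overlap is too small or the sampled variance vanishes.
// [[Rcpp::export]]
double corr_ratio_cpp(IntegerVector fbin, IntegerVector tdim,
                      NumericVector src, IntegerVector sdim,
                      NumericMatrix M, int nbins) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  std::vector<double> n(nbins, 0.0), s(nbins, 0.0), ss(nbins, 0.0);
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  R_xlen_t o = 0;
  for (int k = 0; k < tz; ++k) {
    for (int j = 0; j < ty; ++j) {
      double xb = m01 * j + m02 * k + m03;
      double yb = m11 * j + m12 * k + m13;
      double zb = m21 * j + m22 * k + m23;
      for (int i = 0; i < tx; ++i, ++o) {
        int b = fbin[o];
        if (b < 0) continue;
        double x = m00 * i + xb, y = m10 * i + yb, z = m20 * i + zb;
        if (x < 0 || x > sx - 1 || y < 0 || y > sy - 1 ||
            z < 0 || z > sz - 1)
          continue;
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
        if (x0 > sx - 2) x0 = sx - 2;
        if (y0 > sy - 2) y0 = sy - 2;
        if (z0 > sz - 2) z0 = sz - 2;
        double fx = x - x0, fy = y - y0, fz = z - z0;
        R_xlen_t base = x0 + (R_xlen_t)sx * (y0 + (R_xlen_t)sy * z0);
        R_xlen_t dz = (R_xlen_t)sx * sy;
        double c00 = src[base] * (1 - fx) + src[base + 1] * fx;
        double c10 = src[base + sx] * (1 - fx) + src[base + sx + 1] * fx;
        double c01 = src[base + dz] * (1 - fx) + src[base + dz + 1] * fx;
        double c11 = src[base + dz + sx] * (1 - fx) + src[base + dz + sx + 1] * fx;
        double c0 = c00 * (1 - fy) + c10 * fy;
        double c1 = c01 * (1 - fy) + c11 * fy;
        double v = c0 * (1 - fz) + c1 * fz;
        n[b] += 1.0; s[b] += v; ss[b] += v * v;
      }
    }
  }
  double N = 0, S = 0, SS = 0, within = 0;
  for (int b = 0; b < nbins; ++b) { N += n[b]; S += s[b]; SS += ss[b]; }
  if (N < 64) return NA_REAL;
  double tot = SS - S * S / N;
  if (tot <= 0) return NA_REAL;
  for (int b = 0; b < nbins; ++b)
    if (n[b] > 0) within += ss[b] - s[b] * s[b] / n[b];
  return 1.0 - within / tot;
}

// Normalised mutual information (Studholme) between fixed-image bins and
// the binned trilinearly sampled moving image, over the field-of-view
// overlap. mn/mx give the moving-image binning range.
// [[Rcpp::export]]
double nmi_cpp(IntegerVector fbin, IntegerVector tdim,
               NumericVector src, IntegerVector sdim,
               NumericMatrix M, int nbins, double mn, double mx) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  if (mx <= mn) return NA_REAL;
  const double scale = nbins / (mx - mn);
  std::vector<double> joint((size_t)nbins * nbins, 0.0);
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  R_xlen_t o = 0;
  double N = 0;
  for (int k = 0; k < tz; ++k) {
    for (int j = 0; j < ty; ++j) {
      double xb = m01 * j + m02 * k + m03;
      double yb = m11 * j + m12 * k + m13;
      double zb = m21 * j + m22 * k + m23;
      for (int i = 0; i < tx; ++i, ++o) {
        int b = fbin[o];
        if (b < 0) continue;
        double x = m00 * i + xb, y = m10 * i + yb, z = m20 * i + zb;
        if (x < 0 || x > sx - 1 || y < 0 || y > sy - 1 ||
            z < 0 || z > sz - 1)
          continue;
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
        if (x0 > sx - 2) x0 = sx - 2;
        if (y0 > sy - 2) y0 = sy - 2;
        if (z0 > sz - 2) z0 = sz - 2;
        double fx = x - x0, fy = y - y0, fz = z - z0;
        R_xlen_t base = x0 + (R_xlen_t)sx * (y0 + (R_xlen_t)sy * z0);
        R_xlen_t dz = (R_xlen_t)sx * sy;
        double c00 = src[base] * (1 - fx) + src[base + 1] * fx;
        double c10 = src[base + sx] * (1 - fx) + src[base + sx + 1] * fx;
        double c01 = src[base + dz] * (1 - fx) + src[base + dz + 1] * fx;
        double c11 = src[base + dz + sx] * (1 - fx) + src[base + dz + sx + 1] * fx;
        double c0 = c00 * (1 - fy) + c10 * fy;
        double c1 = c01 * (1 - fy) + c11 * fy;
        double v = c0 * (1 - fz) + c1 * fz;
        int mb = (int)((v - mn) * scale);
        if (mb < 0) mb = 0;
        if (mb >= nbins) mb = nbins - 1;
        joint[(size_t)b * nbins + mb] += 1.0;
        N += 1.0;
      }
    }
  }
  if (N < 64) return NA_REAL;
  std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
  for (int b = 0; b < nbins; ++b)
    for (int m = 0; m < nbins; ++m) {
      double p = joint[(size_t)b * nbins + m] / N;
      pf[b] += p; pm[m] += p;
    }
  double hf = 0, hm = 0, hj = 0;
  for (int b = 0; b < nbins; ++b) {
    if (pf[b] > 0) hf -= pf[b] * std::log(pf[b]);
    if (pm[b] > 0) hm -= pm[b] * std::log(pm[b]);
    for (int m = 0; m < nbins; ++m) {
      double p = joint[(size_t)b * nbins + m] / N;
      if (p > 0) hj -= p * std::log(p);
    }
  }
  if (hj <= 0) return NA_REAL;
  return (hf + hm) / hj;
}
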