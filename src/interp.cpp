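#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Keys cubic convolution kernel, a = -0.5 (reproduces linear ramps exactly)
static inline double keys(double t) {
  t = std::fabs(t);
  if (t < 1.0) return ((1.5 * t - 2.5) * t) * t + 1.0;
  if (t < 2.0) return (((-0.5 * t) + 2.5) * t - 4.0) * t + 2.0;
  return 0.0;
}

static inline double at(const double *src, const int *d, int i, int j, int k) {
  return src[(size_t)i + (size_t)d[0] * ((size_t)j + (size_t)d[1] * (size_t)k)];
}

static double sample_nearest(const double *src, const int *d,
                             double x, double y, double z) {
  int i = clampi((int)std::lround(x), 0, d[0] - 1);
  int j = clampi((int)std::lround(y), 0, d[1] - 1);
  int k = clampi((int)std::lround(z), 0, d[2] - 1);
  return at(src, d, i, j, k);
}

static double sample_trilinear(const double *src, const int *d,
                               double x, double y, double z) {
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  int i1 = clampi(i0 + 1, 0, d[0] - 1), j1 = clampi(j0 + 1, 0, d[1] - 1),
      k1 = clampi(k0 + 1, 0, d[2] - 1);
  i0 = clampi(i0, 0, d[0] - 1); j0 = clampi(j0, 0, d[1] - 1); k0 = clampi(k0, 0, d[2] - 1);
  double c00 = at(src, d, i0, j0, k0) * (1 - fx) + at(src, d, i1, j0, k0) * fx;
  double c10 = at(src, d, i0, j1, k0) * (1 - fx) + at(src, d, i1, j1, k0) * fx;
  double c01 = at(src, d, i0, j0, k1) * (1 - fx) + at(src, d, i1, j0, k1) * fx;
  double c11 = at(src, d, i0, j1, k1) * (1 - fx) + at(src, d, i1, j1, k1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static double sample_cubic(const double *src, const int *d,
                           double x, double y, double z) {
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double acc = 0.0, wsum = 0.0;
  for (int kk = -1; kk <= 2; ++kk) {
    double wz = keys(z - (k0 + kk));
    if (wz == 0.0) continue;
    int k = clampi(k0 + kk, 0, d[2] - 1);
    for (int jj = -1; jj <= 2; ++jj) {
      double wy = keys(y - (j0 + jj));
      if (wy == 0.0) continue;
      int j = clampi(j0 + jj, 0, d[1] - 1);
      for (int ii = -1; ii <= 2; ++ii) {
        double wx = keys(x - (i0 + ii));
        if (wx == 0.0) continue;
        int i = clampi(i0 + ii, 0, d[0] - 1);
        double w = wx * wy * wz;
        acc += w * at(src, d, i, j, k);
        wsum += w;
      }
    }
  }
  return wsum != 0.0 ? acc / wsum : acc;
}

// General gather-style resampler.
//   out(v) = src(A[,1:3] %*% v0 + A[,4] + field(v)),  v0 = 0-based output voxel
// mode: 0 nearest, 1 trilinear, 2 cubic. Out-of-volume samples take
// `background` unless edge_clamp, in which case coordinates are clamped.
// clamp_range limits cubic output to the source [min, max] (overshoot guard).
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector src, IntegerVector sdim, IntegerVector odim,
                       NumericMatrix A, Nullable<NumericVector> field,
                       int mode, double background,
                       bool edge_clamp, bool clamp_range) {
  const int d[3] = { sdim[0], sdim[1], sdim[2] };
  const int od[3] = { odim[0], odim[1], odim[2] };
  const size_t N = (size_t)od[0] * od[1] * od[2];
  if ((size_t)src.size() != (size_t)d[0] * d[1] * d[2])
    stop("source length does not match its dimensions");
  NumericVector out(N);
  const double *s = src.begin();
  const double *f = nullptr;
  if (field.isNotNull()) {
    NumericVector fv(field);
    if ((size_t)fv.size() != 3 * N) stop("field length must be 3 * prod(odim)");
    f = fv.begin();
  }
  double smin = 0.0, smax = 0.0;
  if (clamp_range && mode == 2) {
    smin = *std::min_element(s, s + src.size());
    smax = *std::max_element(s, s + src.size());
  }
  const double a00 = A(0,0), a01 = A(0,1), a02 = A(0,2), a03 = A(0,3);
  const double a10 = A(1,0), a11 = A(1,1), a12 = A(1,2), a13 = A(1,3);
  const double a20 = A(2,0), a21 = A(2,1), a22 = A(2,2), a23 = A(2,3);
  size_t n = 0;
  for (int k = 0; k < od[2]; ++k)
    for (int j = 0; j < od[1]; ++j)
      for (int i = 0; i < od[0]; ++i, ++n) {
        double x = a00 * i + a01 * j + a02 * k + a03;
        double y = a10 * i + a11 * j + a12 * k + a13;
        double z = a20 * i + a21 * j + a22 * k + a23;
        if (f) { x += f[n]; y += f[n + N]; z += f[n + 2 * N]; }
        if (edge_clamp) {
          x = clampd(x, 0, d[0] - 1); y = clampd(y, 0, d[1] - 1); z = clampd(z, 0, d[2] - 1);
        } else if (x < 0 || x > d[0] - 1 || y < 0 || y > d[1] - 1 ||
                   z < 0 || z > d[2] - 1) {
          out[n] = background;
          continue;
        }
        double v;
        if (mode == 0) v = sample_nearest(s, d, x, y, z);
        else if (mode == 1) v = sample_trilinear(s, d, x, y, z);
        else {
          v = sample_cubic(s, d, x, y, z);
          if (clamp_range) v = clampd(v, smin, smax);
        }
        out[n] = v;
      }
  return out;
}

// Block-average downsampling by an integer factor (trailing remainder dropped).
// [[Rcpp::export]]
NumericVector cpp_downsample(NumericVector src, IntegerVector sdim, int factor) {
  const int d[3] = { sdim[0], sdim[1], sdim[2] };
  const int od[3] = { d[0] / factor, d[1] / factor, d[2] / factor };
  if (od[0] < 1 || od[1] < 1 || od[2] < 1) stop("factor too large for volume");
  NumericVector out((size_t)od[0] * od[1] * od[2]);
  out.attr("odim") = IntegerVector::create(od[0], od[1], od[2]);
  const double *s = src.begin();
  const double inv = 1.0 / ((double)factor * factor * factor);
  size_t n = 0;
  for (int k = 0; k < od[2]; ++k)
    for (int j = 0; j < od[1]; ++j)
      for (int i = 0; i < od[0]; ++i, ++n) {
        double acc = 0.0;
        for (int kk = 0; kk < factor; ++kk)
          for (int jj = 0; jj < factor; ++jj)
            for (int ii = 0; ii < factor; ++ii)
              acc += at(s, d, i * factor + ii, j * factor + jj, k * factor + kk);
        out[n] = acc * inv;
      }
  return out;
}

// Separable Gaussian smoothing (replicate edges), sigma in voxels.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector src, IntegerVector sdim, double sigma) {
  const int d[3] = { sdim[0], sdim[1], sdim[2] };
  const size_t N = (size_t)d[0] * d[1] * d[2];
  if (sigma <= 0) return clone(src);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + r];
  }
  for (double &k : ker) k /= s;
  NumericVector a = clone(src), b(N);
  double *pa = a.begin(), *pb = b.begin();
  const size_t str[3] = { 1, (size_t)d[0], (size_t)d[0] * d[1] };
  for (int ax = 0; ax < 3; ++ax) {
    const int n = d[ax];
    const size_t st = str[ax];
    size_t idx = 0;
    for (int k = 0; k < d[2]; ++k)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i, ++idx) {
          const int pos = ax == 0 ? i : (ax == 1 ? j : k);
          double acc = 0.0;
          for (int o = -r; o <= r; ++o) {
            int p = pos + o;
            p = p < 0 ? 0 : (p >= n ? n - 1 : p);
            acc += ker[o + r] * pa[idx + ((size_t)p - pos) * st];
          }
          pb[idx] = acc;
        }
    std::swap(pa, pb);
  }
  if (pa == a.begin()) return a; else return b;
}
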