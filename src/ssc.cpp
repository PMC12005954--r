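#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double vat(const double *v, const int *d, int i, int j, int k) {
  // replicate padding
  i = clampi(i, 0, d[0] - 1); j = clampi(j, 0, d[1] - 1); k = clampi(k, 0, d[2] - 1);
  return v[(size_t)i + (size_t)d[0] * ((size_t)j + (size_t)d[1] * (size_t)k)];
}

// Sum of squared differences between the two cubic patches of radius r
// centred at c1 and c2 (replicate-padded at the volume edge).
static double patch_ssd(const double *v, const int *d,
                        const int *c1, const int *c2, int r) {
  double acc = 0.0;
  for (int kk = -r; kk <= r; ++kk)
    for (int jj = -r; jj <= r; ++jj)
      for (int ii = -r; ii <= r; ++ii) {
        double a = vat(v, d, c1[0] + ii, c1[1] + jj, c1[2] + kk);
        double b = vat(v, d, c2[0] + ii, c2[1] + jj, c2[2] + kk);
        double df = a - b;
        acc += df * df;
      }
  return acc;
}

// [[Rcpp::export]]
double cpp_patch_ssd(NumericVector v, IntegerVector dim,
                     IntegerVector p1, IntegerVector p2, int r) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const int c1[3] = { p1[0], p1[1], p1[2] };
  const int c2[3] = { p2[0], p2[1], p2[2] };
  return patch_ssd(v.begin(), d, c1, c2, r);
}

// Self-similarity context descriptors.
// offsets: 6 x 3 integer neighbourhood offsets; pairs: 12 x 2 (1-based rows of
// offsets). For every voxel x: q^2 = mean of the six patch SSDs S(x, x+o_j)
// floored at qfloor; entry(p) = exp(-S(x+o_a, x+o_b)/q^2); entries quantized
// to 2^bits uniform bins of (0, 1] and packed into one 48-bit code (exactly
// representable in a double).
// [[Rcpp::export]]
List cpp_compute_ssc(NumericVector v, IntegerVector dim,
                     IntegerMatrix offsets, IntegerMatrix pairs,
                     int r, int bits, double qfloor, bool return_cont) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const size_t N = (size_t)d[0] * d[1] * d[2];
  if ((size_t)v.size() != N) stop("volume length does not match dim");
  const int no = offsets.nrow(), np = pairs.nrow();
  if (bits * np > 52) stop("packed code would exceed exact double range");
  const double levels = (double)(1 << bits);
  NumericVector packed(N), qsq(N);
  NumericMatrix cont = return_cont ? NumericMatrix(np, N) : NumericMatrix(0, 0);
  const double *src = v.begin();
  size_t n = 0;
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i, ++n) {
        const int c0[3] = { i, j, k };
        double snbr[16];
        double q2 = 0.0;
        for (int o = 0; o < no; ++o) {
          const int co[3] = { i + offsets(o, 0), j + offsets(o, 1), k + offsets(o, 2) };
          snbr[o] = patch_ssd(src, d, c0, co, r);
          q2 += snbr[o];
        }
        q2 /= no;
        if (q2 < qfloor) q2 = qfloor;
        qsq[n] = q2;
        uint64_t code = 0;
        for (int p = 0; p < np; ++p) {
          const int a = pairs(p, 0) - 1, b = pairs(p, 1) - 1;
          const int ca[3] = { i + offsets(a, 0), j + offsets(a, 1), k + offsets(a, 2) };
          const int cb[3] = { i + offsets(b, 0), j + offsets(b, 1), k + offsets(b, 2) };
          double s = patch_ssd(src, d, ca, cb, r);
          double dv = std::exp(-s / q2);
          if (return_cont) cont(p, n) = dv;
          int q = (int)std::ceil(dv * levels) - 1;
          q = clampi(q, 0, (int)levels - 1);
          code |= ((uint64_t)q) << (bits * p);
        }
        packed[n] = (double)code;
      }
  List out = List::create(_["packed"] = packed, _["qsq"] = qsq);
  if (return_cont) out["cont"] = cont;
  return out;
}

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

// Normalized Hamming distance between descriptor codes at voxel `at` in a and
// voxel `at + disp` (replicate-clamped) in b. Voxels are 0-based.
// [[Rcpp::export]]
double cpp_hamming_at(NumericVector pa, NumericVector pb, IntegerVector dim,
                      IntegerVector at, IntegerVector disp, int totalbits) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  int i = clampi(at[0], 0, d[0] - 1), j = clampi(at[1], 0, d[1] - 1),
      k = clampi(at[2], 0, d[2] - 1);
  int i2 = clampi(at[0] + disp[0], 0, d[0] - 1),
      j2 = clampi(at[1] + disp[1], 0, d[1] - 1),
      k2 = clampi(at[2] + disp[2], 0, d[2] - 1);
  size_t n1 = (size_t)i + (size_t)d[0] * ((size_t)j + (size_t)d[1] * (size_t)k);
  size_t n2 = (size_t)i2 + (size_t)d[0] * ((size_t)j2 + (size_t)d[1] * (size_t)k2);
  uint64_t a = (uint64_t)pa[n1], b = (uint64_t)pb[n2];
  return (double)popcount64(a ^ b) / (double)totalbits;
}
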