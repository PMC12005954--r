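#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

static inline size_t lin(const int *d, int i, int j, int k) {
  return (size_t)i + (size_t)d[0] * ((size_t)j + (size_t)d[1] * (size_t)k);
}

struct Cand { int dx, dy, dz, cube; };

// Candidates of the (2r+1)^3 cube sorted by (|d|^2, dx, dy, dz) so that a
// strict-< scan implements the smallest-norm-then-lexicographic tie-break.
static std::vector<Cand> sorted_cube(int radius) {
  std::vector<Cand> cands;
  const int w = 2 * radius + 1;
  for (int dz = -radius; dz <= radius; ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx) {
        Cand c;
        c.dx = dx; c.dy = dy; c.dz = dz;
        c.cube = (dx + radius) + w * ((dy + radius) + w * (dz + radius));
        cands.push_back(c);
      }
  std::stable_sort(cands.begin(), cands.end(), [](const Cand &a, const Cand &b) {
    int na = a.dx * a.dx + a.dy * a.dy + a.dz * a.dz;
    int nb = b.dx * b.dx + b.dy * b.dy + b.dz * b.dz;
    if (na != nb) return na < nb;
    if (a.dx != b.dx) return a.dx < b.dx;
    if (a.dy != b.dy) return a.dy < b.dy;
    return a.dz < b.dz;
  });
  return cands;
}

// Exhaustive integer-displacement block matching on packed descriptor codes.
// centers are 0-based block centers; cost = mean normalized Hamming distance
// over the (2*bhalf+1)^3 block. Returns integer argmin displacement per block
// (ties: smallest norm, then lexicographic), optional separable parabolic
// sub-voxel refinement, and the best cost.
// [[Rcpp::export]]
List cpp_block_match(NumericVector packedF, NumericVector packedM,
                     IntegerVector dim, IntegerMatrix centers,
                     int bhalf, int radius, int totalbits, bool refine) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const int nb = centers.nrow();
  const std::vector<Cand> cands = sorted_cube(radius);
  const int w = 2 * radius + 1;
  const int ncand = w * w * w;
  const double *pf = packedF.begin();
  const double *pm = packedM.begin();
  IntegerMatrix best(nb, 3);
  NumericMatrix refined(nb, 3);
  NumericVector score(nb);
  std::vector<double> cube(ncand);
  const double norm = 1.0 / (double)totalbits;
  for (int b = 0; b < nb; ++b) {
    const int cx = centers(b, 0), cy = centers(b, 1), cz = centers(b, 2);
    double bestCost = R_PosInf;
    int bi = 0;
    for (int ci = 0; ci < ncand; ++ci) {
      const Cand &c = cands[ci];
      long bitsum = 0;
      int nvox = 0;
      for (int kk = -bhalf; kk <= bhalf; ++kk)
        for (int jj = -bhalf; jj <= bhalf; ++jj)
          for (int ii = -bhalf; ii <= bhalf; ++ii) {
            int x = clampi(cx + ii, 0, d[0] - 1);
            int y = clampi(cy + jj, 0, d[1] - 1);
            int z = clampi(cz + kk, 0, d[2] - 1);
            int x2 = clampi(x + c.dx, 0, d[0] - 1);
            int y2 = clampi(y + c.dy, 0, d[1] - 1);
            int z2 = clampi(z + c.dz, 0, d[2] - 1);
            uint64_t a = (uint64_t)pf[lin(d, x, y, z)];
            uint64_t m = (uint64_t)pm[lin(d, x2, y2, z2)];
            bitsum += popcount64(a ^ m);
            ++nvox;
          }
      double cost = (double)bitsum * norm / (double)nvox;
      cube[c.cube] = cost;
      if (cost < bestCost) { bestCost = cost; bi = ci; }
    }
    const Cand &bc = cands[bi];
    best(b, 0) = bc.dx; best(b, 1) = bc.dy; best(b, 2) = bc.dz;
    score[b] = bestCost;
    double rf[3] = { (double)bc.dx, (double)bc.dy, (double)bc.dz };
    if (refine) {
      const int bd[3] = { bc.dx + radius, bc.dy + radius, bc.dz + radius };
      const int stride[3] = { 1, w, w * w };
      for (int ax = 0; ax < 3; ++ax) {
        if (bd[ax] > 0 && bd[ax] < w - 1) {
          int base = bd[0] + w * (bd[1] + w * bd[2]);
          double cm = cube[base - stride[ax]];
          double c0 = cube[base];
          double cp = cube[base + stride[ax]];
          double den = cm - 2.0 * c0 + cp;
          // only refine strict local minima; plateaus stay on the integer grid
          if (cm > c0 && cp > c0 && den > 1e-12) {
            double off = 0.5 * (cm - cp) / den;
            if (off > 0.5) off = 0.5;
            if (off < -0.5) off = -0.5;
            rf[ax] += off;
          }
        }
      }
    }
    refined(b, 0) = rf[0]; refined(b, 1) = rf[1]; refined(b, 2) = rf[2];
  }
  return List::create(_["disp"] = best, _["refined"] = refined, _["score"] = score);
}

// Data term for the discrete deformable stage: mean normalized Hamming
// distance over the (2*phalf+1)^3 patch around each 0-based control point,
// between fixed codes and moving codes displaced by each candidate.
// [[Rcpp::export]]
NumericMatrix cpp_data_costs(NumericVector packedF, NumericVector packedM,
                             IntegerVector dim, IntegerMatrix cps,
                             IntegerMatrix cands, int phalf, int totalbits) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const int ncp = cps.nrow(), nc = cands.nrow();
  const double *pf = packedF.begin();
  const double *pm = packedM.begin();
  NumericMatrix costs(ncp, nc);
  const double norm = 1.0 / (double)totalbits;
  for (int c = 0; c < ncp; ++c) {
    const int cx = cps(c, 0), cy = cps(c, 1), cz = cps(c, 2);
    for (int ci = 0; ci < nc; ++ci) {
      const int dx = cands(ci, 0), dy = cands(ci, 1), dz = cands(ci, 2);
      long bitsum = 0;
      int nvox = 0;
      for (int kk = -phalf; kk <= phalf; ++kk)
        for (int jj = -phalf; jj <= phalf; ++jj)
          for (int ii = -phalf; ii <= phalf; ++ii) {
            int x = clampi(cx + ii, 0, d[0] - 1);
            int y = clampi(cy + jj, 0, d[1] - 1);
            int z = clampi(cz + kk, 0, d[2] - 1);
            int x2 = clampi(x + dx, 0, d[0] - 1);
            int y2 = clampi(y + dy, 0, d[1] - 1);
            int z2 = clampi(z + dz, 0, d[2] - 1);
            uint64_t a = (uint64_t)pf[lin(d, x, y, z)];
            uint64_t m = (uint64_t)pm[lin(d, x2, y2, z2)];
            bitsum += popcount64(a ^ m);
            ++nvox;
          }
      costs(c, ci) = (double)bitsum * norm / (double)nvox;
    }
  }
  return costs;
}

// Mean intensity in the (2*phalf+1)^3 patch around each 0-based point.
// [[Rcpp::export]]
NumericVector cpp_patch_means(NumericVector v, IntegerVector dim,
                              IntegerMatrix cps, int phalf) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const int ncp = cps.nrow();
  const double *s = v.begin();
  NumericVector out(ncp);
  for (int c = 0; c < ncp; ++c) {
    const int cx = cps(c, 0), cy = cps(c, 1), cz = cps(c, 2);
    double acc = 0.0;
    int nvox = 0;
    for (int kk = -phalf; kk <= phalf; ++kk)
      for (int jj = -phalf; jj <= phalf; ++jj)
        for (int ii = -phalf; ii <= phalf; ++ii) {
          int x = clampi(cx + ii, 0, d[0] - 1);
          int y = clampi(cy + jj, 0, d[1] - 1);
          int z = clampi(cz + kk, 0, d[2] - 1);
          acc += s[lin(d, x, y, z)];
          ++nvox;
        }
    out[c] = acc / nvox;
  }
  return out;
}
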