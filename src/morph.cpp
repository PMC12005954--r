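#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Binary dilation by an arbitrary structuring element given as offsets.
// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dim,
                         IntegerMatrix offsets) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const size_t N = (size_t)d0 * d1 * d2;
  LogicalVector out(N);
  const int no = offsets.nrow();
  size_t n = 0;
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j)
      for (int i = 0; i < d0; ++i, ++n) {
        if (!mask[n]) continue;
        for (int o = 0; o < no; ++o) {
          int x = i + offsets(o, 0), y = j + offsets(o, 1), z = k + offsets(o, 2);
          if (x < 0 || x >= d0 || y < 0 || y >= d1 || z < 0 || z >= d2) continue;
          out[(size_t)x + (size_t)d0 * ((size_t)y + (size_t)d1 * (size_t)z)] = true;
        }
      }
  return out;
}

// 6-connected component labeling (BFS, labels assigned in scan order).
// [[Rcpp::export]]
IntegerVector cpp_components(LogicalVector mask, IntegerVector dim) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const size_t N = (size_t)d0 * d1 * d2;
  IntegerVector labels(N);
  int next = 0;
  std::queue<size_t> q;
  const int off0[6] = { -1, 1, 0, 0, 0, 0 };
  const int off1[6] = { 0, 0, -1, 1, 0, 0 };
  const int off2[6] = { 0, 0, 0, 0, -1, 1 };
  for (size_t s = 0; s < N; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    labels[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      size_t n = q.front(); q.pop();
      int i = (int)(n % d0);
      int j = (int)((n / d0) % d1);
      int k = (int)(n / ((size_t)d0 * d1));
      for (int o = 0; o < 6; ++o) {
        int x = i + off0[o], y = j + off1[o], z = k + off2[o];
        if (x < 0 || x >= d0 || y < 0 || y >= d1 || z < 0 || z >= d2) continue;
        size_t t = (size_t)x + (size_t)d0 * ((size_t)y + (size_t)d1 * (size_t)z);
        if (mask[t] && labels[t] == 0) { labels[t] = next; q.push(t); }
      }
    }
  }
  return labels;
}

// Directed Hausdorff distance max_p min_g ||p - g|| between point sets (rows, mm).
// [[Rcpp::export]]
double cpp_directed_hausdorff(NumericMatrix P, NumericMatrix G) {
  const int np = P.nrow(), ng = G.nrow();
  if (np == 0 || ng == 0) stop("empty point set");
  double hmax = 0.0;
  for (int p = 0; p < np; ++p) {
    double px = P(p, 0), py = P(p, 1), pz = P(p, 2);
    double dmin = R_PosInf;
    for (int g = 0; g < ng; ++g) {
      double dx = px - G(g, 0), dy = py - G(g, 1), dz = pz - G(g, 2);
      double dd = dx * dx + dy * dy + dz * dz;
      if (dd < dmin) {
        dmin = dd;
        if (dmin <= hmax) break;  // cannot raise the max
      }
    }
    if (dmin > hmax) hmax = dmin;
  }
  return std::sqrt(hmax);
}
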