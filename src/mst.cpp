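#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Union-find for Kruskal
struct DSU {
  std::vector<int> p;
  DSU(int n) : p(n) { std::iota(p.begin(), p.end(), 0); }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    p[b] = a; return true;
  }
};

// 1D weighted squared-distance lower envelope (Felzenszwalb-Huttenlocher):
// out[p] = min_q ( g[q] + w * (p - q)^2 ). Exact for w > 0.
static void dt1d(const double *g, double *out, int n, double w,
                 std::vector<int> &vbuf, std::vector<double> &zbuf) {
  if (w <= 0.0) {
    double m = g[0];
    for (int i = 1; i < n; ++i) if (g[i] < m) m = g[i];
    for (int i = 0; i < n; ++i) out[i] = m;
    return;
  }
  int *vtx = vbuf.data();
  double *z = zbuf.data();
  int k = 0;
  vtx[0] = 0;
  z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int vk = vtx[k];
      s = ((g[q] + w * q * q) - (g[vk] + w * vk * vk)) / (2.0 * w * (q - vk));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    vtx[k] = q;
    z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int p = 0; p < n; ++p) {
    while (z[k + 1] < p) ++k;
    int vk = vtx[k];
    double dq = p - vk;
    out[p] = g[vk] + w * dq * dq;
  }
}

// Exact minimization of
//   sum_c cost(c, d_c) + alpha * sum_{(c,p) in MST} ||d_c - d_p||^2 / quant^2
// over the displacement labeling of a 6-connected control-point lattice.
// The MST uses edge weights = squared difference of per-node features (local
// intensity means); dynamic programming over the tree is exact. When the
// candidates form a full cube grid in steps of `quant` (is_grid), messages use
// the separable lower-envelope transform; otherwise O(m^2) per edge.
// Ties are broken toward the smallest displacement norm, then lexicographic.
// [[Rcpp::export]]
List cpp_mst_optimize(NumericMatrix costs, IntegerVector ldim,
                      NumericMatrix cands, double alpha, double quant,
                      NumericVector feats,
                      bool is_grid, IntegerVector gdim, IntegerMatrix gidx,
                      double dt_weight) {
  const int n = costs.nrow(), m = costs.ncol();
  const int l0 = ldim[0], l1 = ldim[1], l2 = ldim[2];
  if (n != l0 * l1 * l2) stop("lattice dims do not match cost rows");
  if ((int)feats.size() != n) stop("feats length mismatch");
  if (cands.nrow() != m) stop("candidate count mismatch");

  // --- edges of the 6-connected lattice (3 axis directions) ---
  struct Edge { int u, v; double w; };
  std::vector<Edge> edges;
  edges.reserve((size_t)3 * n);
  auto node = [&](int i, int j, int k) { return i + l0 * (j + l1 * k); };
  for (int k = 0; k < l2; ++k)
    for (int j = 0; j < l1; ++j)
      for (int i = 0; i < l0; ++i) {
        int u = node(i, j, k);
        if (i + 1 < l0) { double dfe = feats[u] - feats[node(i+1,j,k)]; edges.push_back({u, node(i+1,j,k), dfe*dfe}); }
        if (j + 1 < l1) { double dfe = feats[u] - feats[node(i,j+1,k)]; edges.push_back({u, node(i,j+1,k), dfe*dfe}); }
        if (k + 1 < l2) { double dfe = feats[u] - feats[node(i,j,k+1)]; edges.push_back({u, node(i,j,k+1), dfe*dfe}); }
      }

  // --- Kruskal MST (stable: ties broken by construction order) ---
  std::vector<int> order(edges.size());
  std::iota(order.begin(), order.end(), 0);
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    return edges[a].w < edges[b].w;
  });
  DSU dsu(n);
  std::vector<std::vector<int>> adj(n);
  int nmst = 0;
  for (int ei : order) {
    if (dsu.unite(edges[ei].u, edges[ei].v)) {
      adj[edges[ei].u].push_back(edges[ei].v);
      adj[edges[ei].v].push_back(edges[ei].u);
      ++nmst;
    }
  }
  if (n > 1 && nmst != n - 1) stop("control lattice is disconnected");

  // --- BFS order from the lattice-center root ---
  const int root = node((l0 - 1) / 2, (l1 - 1) / 2, (l2 - 1) / 2);
  std::vector<int> bfs; bfs.reserve(n);
  std::vector<int> parent(n, -1);
  std::vector<char> seen(n, 0);
  bfs.push_back(root); seen[root] = 1;
  for (size_t h = 0; h < bfs.size(); ++h) {
    int u = bfs[h];
    for (int v : adj[u]) if (!seen[v]) { seen[v] = 1; parent[v] = u; bfs.push_back(v); }
  }

  // --- candidate priority order for tie-breaking ---
  std::vector<int> prio(m);
  std::iota(prio.begin(), prio.end(), 0);
  std::stable_sort(prio.begin(), prio.end(), [&](int a, int b) {
    double na = cands(a,0)*cands(a,0) + cands(a,1)*cands(a,1) + cands(a,2)*cands(a,2);
    double nb = cands(b,0)*cands(b,0) + cands(b,1)*cands(b,1) + cands(b,2)*cands(b,2);
    if (na != nb) return na < nb;
    if (cands(a,0) != cands(b,0)) return cands(a,0) < cands(b,0);
    if (cands(a,1) != cands(b,1)) return cands(a,1) < cands(b,1);
    return cands(a,2) < cands(b,2);
  });

  const double q2 = quant * quant;
  auto pen = [&](int a, int b) {
    double dx = cands(a,0) - cands(b,0);
    double dy = cands(a,1) - cands(b,1);
    double dz = cands(a,2) - cands(b,2);
    return alpha * (dx*dx + dy*dy + dz*dz) / q2;
  };

  // --- leaves-to-root message passing: B_v = cost_v + sum child messages ---
  std::vector<std::vector<double>> B(n, std::vector<double>(m));
  for (int v = 0; v < n; ++v)
    for (int c = 0; c < m; ++c) B[v][c] = costs(v, c);

  const int g0 = is_grid ? gdim[0] : 0, g1 = is_grid ? gdim[1] : 0,
            g2 = is_grid ? gdim[2] : 0;
  std::vector<double> grid1, grid2, line_in, line_out;
  std::vector<int> vbuf; std::vector<double> zbuf;
  if (is_grid) {
    grid1.resize(m); grid2.resize(m);
    int mx = std::max(g0, std::max(g1, g2));
    line_in.resize(mx); line_out.resize(mx);
    vbuf.resize(mx); zbuf.resize(mx + 1);
  }

  auto message = [&](const std::vector<double> &Bv, std::vector<double> &msg) {
    if (is_grid) {
      // scatter into the candidate cube, 3 separable DT passes, gather back
      for (int c = 0; c < m; ++c)
        grid1[gidx(c,0) + g0 * (gidx(c,1) + g1 * gidx(c,2))] = Bv[c];
      // pass along x
      for (int k = 0; k < g2; ++k)
        for (int j = 0; j < g1; ++j) {
          for (int i = 0; i < g0; ++i) line_in[i] = grid1[i + g0*(j + g1*k)];
          dt1d(line_in.data(), line_out.data(), g0, dt_weight, vbuf, zbuf);
          for (int i = 0; i < g0; ++i) grid2[i + g0*(j + g1*k)] = line_out[i];
        }
      // pass along y
      for (int k = 0; k < g2; ++k)
        for (int i = 0; i < g0; ++i) {
          for (int j = 0; j < g1; ++j) line_in[j] = grid2[i + g0*(j + g1*k)];
          dt1d(line_in.data(), line_out.data(), g1, dt_weight, vbuf, zbuf);
          for (int j = 0; j < g1; ++j) grid1[i + g0*(j + g1*k)] = line_out[j];
        }
      // pass along z
      for (int j = 0; j < g1; ++j)
        for (int i = 0; i < g0; ++i) {
          for (int k = 0; k < g2; ++k) line_in[k] = grid1[i + g0*(j + g1*k)];
          dt1d(line_in.data(), line_out.data(), g2, dt_weight, vbuf, zbuf);
          for (int k = 0; k < g2; ++k) grid2[i + g0*(j + g1*k)] = line_out[k];
        }
      for (int c = 0; c < m; ++c)
        msg[c] = grid2[gidx(c,0) + g0 * (gidx(c,1) + g1 * gidx(c,2))];
    } else {
      for (int p = 0; p < m; ++p) {
        double best = R_PosInf;
        for (int c = 0; c < m; ++c) {
          double val = Bv[c] + pen(c, p);
          if (val < best) best = val;
        }
        msg[p] = best;
      }
    }
  };

  std::vector<double> msg(m);
  for (int h = n - 1; h >= 1; --h) {
    int v = bfs[h];
    message(B[v], msg);
    std::vector<double> &Bp = B[parent[v]];
    for (int c = 0; c < m; ++c) Bp[c] += msg[c];
  }

  // --- root argmin + top-down backtracking, tie-broken via prio order ---
  std::vector<int> sel(n, 0);
  {
    double best = R_PosInf;
    for (int pi = 0; pi < m; ++pi) {
      int c = prio[pi];
      if (B[root][c] < best) { best = B[root][c]; sel[root] = c; }
    }
  }
  for (size_t h = 1; h < bfs.size(); ++h) {
    int v = bfs[h];
    int dp = sel[parent[v]];
    double best = R_PosInf;
    for (int pi = 0; pi < m; ++pi) {
      int c = prio[pi];
      double val = B[v][c] + pen(c, dp);
      if (val < best) { best = val; sel[v] = c; }
    }
  }

  // --- objective of the selected labeling (data + regularizer over MST) ---
  double obj = 0.0;
  for (int v = 0; v < n; ++v) obj += costs(v, sel[v]);
  for (int v = 0; v < n; ++v)
    if (parent[v] >= 0) obj += pen(sel[v], sel[parent[v]]);

  NumericMatrix disp(n, 3);
  IntegerVector selected(n);
  for (int v = 0; v < n; ++v) {
    selected[v] = sel[v] + 1;
    disp(v, 0) = cands(sel[v], 0);
    disp(v, 1) = cands(sel[v], 1);
    disp(v, 2) = cands(sel[v], 2);
  }
  return List::create(_["selected"] = selected, _["disp"] = disp,
                      _["objective"] = obj);
}
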