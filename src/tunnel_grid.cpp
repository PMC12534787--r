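#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Clearance field of a voxel grid: for every voxel center, the distance to
// the nearest atom center, saturated at `cap`. Atom-centric update: each atom
// only touches voxels inside its cap-sized neighbourhood, so the cost is
// n_atoms * (2*cap/spacing)^3 rather than n_voxels * n_atoms.
// Voxel (i,j,k) has center origin + (i+0.5)*spacing and linear index
// i + nx*(j + ny*k), all 0-based.
// [[Rcpp::export]]
NumericVector grid_distance_field(NumericMatrix atoms, NumericVector origin,
                                  double spacing, IntegerVector dims,
                                  double cap) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector field(n, cap);
  std::vector<double> f2(n, cap * cap);
  const int r = (int)std::ceil(cap / spacing) + 1;

  for (int a = 0; a < atoms.nrow(); ++a) {
    const double ax = atoms(a, 0), ay = atoms(a, 1), az = atoms(a, 2);
    const int ci = (int)std::floor((ax - origin[0]) / spacing);
    const int cj = (int)std::floor((ay - origin[1]) / spacing);
    const int ck = (int)std::floor((az - origin[2]) / spacing);
    const int i0 = std::max(0, ci - r), i1 = std::min(nx - 1, ci + r);
    const int j0 = std::max(0, cj - r), j1 = std::min(ny - 1, cj + r);
    const int k0 = std::max(0, ck - r), k1 = std::min(nz - 1, ck + r);
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + (k + 0.5) * spacing - az;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + (j + 0.5) * spacing - ay;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 >= cap * cap) continue;
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + (i + 0.5) * spacing - ax;
          const double d2 = dx * dx + dyz2;
          if (d2 < f2[base + i]) f2[base + i] = d2;
        }
      }
    }
  }
  for (R_xlen_t v = 0; v < n; ++v) field[v] = std::sqrt(f2[v]);
  return field;
}

struct Node {
  double clearance;
  int idx;
};
struct NodeCmp {
  // max-heap on clearance; equal clearances pop the smaller index first,
  // making the search deterministic for any queue content
  bool operator()(const Node& a, const Node& b) const {
    if (a.clearance != b.clearance) return a.clearance < b.clearance;
    return a.idx > b.idx;
  }
};

// Widest-bottleneck (max-min clearance) Dijkstra over a 6-connected voxel
// grid. Expansion runs through open, non-target voxels only; target voxels
// absorb (a path ends on first contact with the solvent shell). Returns, for
// every voxel, the best achievable bottleneck from the source (-1 if
// unreached) and the predecessor voxel (-1 for the source / unreached).
// `neigh_order` permutes the six axis neighbours, the caller's seed-derived
// tie-break.
// [[Rcpp::export]]
List widest_path_grid(NumericVector field, IntegerVector dims,
                      LogicalVector open, LogicalVector target,
                      int source, IntegerVector neigh_order) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector best(n, -1.0);
  IntegerVector parent(n, -1);
  if (source < 0 || source >= n || !open[source])
    return List::create(_["best"] = best, _["parent"] = parent);

  const int offs[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                          {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};
  std::priority_queue<Node, std::vector<Node>, NodeCmp> pq;
  best[source] = field[source];
  pq.push({best[source], source});

  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    const int u = nd.idx;
    if (nd.clearance < best[u]) continue;  // stale entry
    if (target[u]) continue;               // absorbing state
    const int ux = u % nx, uy = (u / nx) % ny, uz = u / (nx * ny);
    for (int t = 0; t < 6; ++t) {
      const int* o = offs[neigh_order[t]];
      const int vx = ux + o[0], vy = uy + o[1], vz = uz + o[2];
      if (vx < 0 || vx >= nx || vy < 0 || vy >= ny || vz < 0 || vz >= nz)
        continue;
      const int v = vx + nx * (vy + ny * vz);
      if (!open[v]) continue;
      const double cand = std::min(nd.clearance, field[v]);
      if (cand > best[v]) {
        best[v] = cand;
        parent[v] = u;
        pq.push({cand, v});
      }
    }
  }
  return List::create(_["best"] = best, _["parent"] = parent);
}

// 6-connected flood fill from all box-boundary voxels through `mask`;
// returns the component of mask reachable from the boundary (bulk solvent).
// [[Rcpp::export]]
LogicalVector flood_from_boundary(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  std::vector<int> stack;
  stack.reserve(1 << 16);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1)
          continue;
        const int v = i + nx * (j + ny * k);
        if (mask[v] && !out[v]) { out[v] = true; stack.push_back(v); }
      }
  const int offs[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                          {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};
  while (!stack.empty()) {
    const int u = stack.back();
    stack.pop_back();
    const int ux = u % nx, uy = (u / nx) % ny, uz = u / (nx * ny);
    for (int t = 0; t < 6; ++t) {
      const int vx = ux + offs[t][0], vy = uy + offs[t][1],
                vz = uz + offs[t][2];
      if (vx < 0 || vx >= nx || vy < 0 || vy >= ny || vz < 0 || vz >= nz)
        continue;
      const int v = vx + nx * (vy + ny * vz);
      if (mask[v] && !out[v]) { out[v] = true; stack.push_back(v); }
    }
  }
  return out;
}

// `steps` rounds of 6-connected dilation of a voxel mask.
// [[Rcpp::export]]
LogicalVector dilate_mask(LogicalVector mask, IntegerVector dims, int steps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> cur(n), nxt(n);
  for (R_xlen_t v = 0; v < n; ++v) cur[v] = mask[v];
  for (int s = 0; s < steps; ++s) {
    nxt = cur;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          if (cur[v]) continue;
          if ((i > 0 && cur[v - 1]) || (i < nx - 1 && cur[v + 1]) ||
              (j > 0 && cur[v - nx]) || (j < ny - 1 && cur[v + nx]) ||
              (k > 0 && cur[v - (R_xlen_t)nx * ny]) ||
              (k < nz - 1 && cur[v + (R_xlen_t)nx * ny]))
            nxt[v] = 1;
        }
    cur.swap(nxt);
  }
  LogicalVector out(n);
  for (R_xlen_t v = 0; v < n; ++v) out[v] = cur[v] != 0;
  return out;
}
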