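// Grid flood primitives for the abdominal segmentation pipeline:
// connected-component labelling and a seeded compact watershed.
// Both operate on 3D arrays in R's column-major layout.

#include <Rcpp.h>
#include <array>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  Grid(IntegerVector d) : nx(d[0]), ny(d[1]), nz(d[2]) {}
  inline int size() const { return nx * ny * nz; }
  inline void coords(int idx, int &x, int &y, int &z) const {
    x = idx % nx;
    y = (idx / nx) % ny;
    z = idx / (nx * ny);
  }
};

// 6-connected neighbour offsets (face adjacency); 26-connectivity adds
// edge/corner moves. Returned as coordinate deltas.
const int OFF6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};

} // namespace

// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  Grid g(dims);
  const int n = g.size();
  IntegerVector out(n, 0);
  std::vector<int> stack;
  std::vector<std::array<int,3>> offs;
  if (connectivity == 6) {
    for (auto &o : OFF6) offs.push_back({o[0], o[1], o[2]});
  } else {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz)
          if (dx || dy || dz) offs.push_back({dx, dy, dz});
  }
  int lab = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || out[i]) continue;
    ++lab;
    out[i] = lab;
    stack.push_back(i);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int x, y, z; g.coords(cur, x, y, z);
      for (auto &o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= g.nx || yy >= g.ny || zz >= g.nz)
          continue;
        int j = xx + g.nx * (yy + g.ny * zz);
        if (mask[j] && !out[j]) { out[j] = lab; stack.push_back(j); }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

namespace {

struct QEntry {
  double prio;
  long order;   // FIFO tie-break for plateau stability
  int idx;
  int seed;     // originating seed voxel (for the compactness distance)
  int label;
};

struct QCmp {
  bool operator()(const QEntry &a, const QEntry &b) const {
    if (a.prio != b.prio) return a.prio > b.prio;
    return a.order > b.order;
  }
};

} // namespace

// Seeded compact watershed: priority-flood on `height` (typically a gradient
// magnitude), restricted to `mask`, with an additive compactness penalty
// proportional to the physical distance (mm) from the originating seed voxel.
// Markers: 0 = unseeded, >0 = region label. Returns the grown label image.
// [[Rcpp::export(name = ".compact_watershed")]]
IntegerVector compact_watershed(NumericVector height, IntegerVector markers,
                                LogicalVector mask, IntegerVector dims,
                                NumericVector spacing, double compactness) {
  Grid g(dims);
  const int n = g.size();
  IntegerVector out(n, 0);
  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  long order = 0;
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  auto dist_mm = [&](int a, int b) {
    int ax, ay, az, bx, by, bz;
    g.coords(a, ax, ay, az);
    g.coords(b, bx, by, bz);
    double dx = (ax - bx) * sx, dy = (ay - by) * sy, dz = (az - bz) * sz;
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  };

  for (int i = 0; i < n; ++i) {
    if (markers[i] > 0 && mask[i]) {
      out[i] = markers[i];
      pq.push({height[i], order++, i, i, markers[i]});
    }
  }
  while (!pq.empty()) {
    QEntry e = pq.top(); pq.pop();
    int x, y, z; g.coords(e.idx, x, y, z);
    for (auto &o : OFF6) {
      int xx = x + o[0], yy = y + o[1], zz = z + o[2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= g.nx || yy >= g.ny || zz >= g.nz)
        continue;
      int j = xx + g.nx * (yy + g.ny * zz);
      if (!mask[j] || out[j]) continue;
      out[j] = e.label;
      double prio = height[j] + compactness * dist_mm(j, e.seed);
      pq.push({prio, order++, j, e.seed, e.label});
    }
  }
  out.attr("dim") = dims;
  return out;
}
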