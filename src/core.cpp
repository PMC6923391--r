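#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Volumes are R arrays in (z, y, x) order, column-major: the linear index is
// z + nz*(y + ny*x). All kernels below work on that layout.

static inline void make_offsets(int connectivity, int nz, int ny, int nx,
                                std::vector<std::array<int,3>>& offs) {
  offs.clear();
  if (connectivity == 6) {
    offs = {{{1,0,0}},{{-1,0,0}},{{0,1,0}},{{0,-1,0}},{{0,0,1}},{{0,0,-1}}};
  } else {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if (dz || dy || dx) offs.push_back({{dz,dy,dx}});
  }
}

// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector out(n, 0);
  std::vector<std::array<int,3>> offs;
  make_offsets(connectivity, nz, ny, nx, offs);
  std::vector<R_xlen_t> stack;
  int next_id = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || out[start] != 0) continue;
    ++next_id;
    out[start] = next_id;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int x = (int)(cur / ((R_xlen_t)nz * ny));
      int rem = (int)(cur % ((R_xlen_t)nz * ny));
      int y = rem / nz, z = rem % nz;
      for (auto& o : offs) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t idx = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[idx] && out[idx] == 0) {
          out[idx] = next_id;
          stack.push_back(idx);
        }
      }
    }
  }
  return out;
}

// 1D squared-distance transform (lower envelope of parabolas), anisotropic:
// sample positions are i*w for voxel index i and axis spacing w.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double w, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -HUGE_VAL;
  z[1] = HUGE_VAL;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = HUGE_VAL;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// Euclidean distance (nm or voxels, per `spacing`) from each foreground voxel
// to the nearest background voxel; 0 on background.
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double BIG = 1e30;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? BIG : 0.0;

  std::vector<double> f, out;
  // pass along z
  f.resize(nz); out.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int z = 0; z < nz; ++z) f[z] = d[base + z];
      dt1d(f, out, spacing[0], nz);
      for (int z = 0; z < nz; ++z) d[base + z] = out[z];
    }
  // pass along y
  f.resize(ny); out.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y)
        f[y] = d[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
      dt1d(f, out, spacing[1], ny);
      for (int y = 0; y < ny; ++y)
        d[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = out[y];
    }
  // pass along x
  f.resize(nx); out.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x)
        f[x] = d[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
      dt1d(f, out, spacing[2], nx);
      for (int x = 0; x < nx; ++x)
        d[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = std::sqrt(out[x]);
    }
  return d;
}

struct FloodNode {
  double height;     // distance-transform value: flood high first
  uint64_t seq;      // discovery order: BFS among equal heights
  int id;
  R_xlen_t idx;
};
struct FloodCmp {
  bool operator()(const FloodNode& a, const FloodNode& b) const {
    if (a.height != b.height) return a.height < b.height;  // max-heap on height
    if (a.seq != b.seq) return a.seq > b.seq;              // FIFO tie-break
    return a.id > b.id;                                    // then lowest id
  }
};

// Marker-based flood on descending `height` (negative-distance ascent).
// [[Rcpp::export(name = ".watershed_flood_cpp")]]
IntegerVector watershed_flood_cpp(LogicalVector mask, NumericVector height,
                                  IntegerVector markers, IntegerVector dims,
                                  int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector out(n, 0);
  std::vector<std::array<int,3>> offs;
  make_offsets(connectivity, nz, ny, nx, offs);
  std::priority_queue<FloodNode, std::vector<FloodNode>, FloodCmp> pq;
  uint64_t seq = 0;

  // Seed the queue in ascending marker id, then ascending linear index.
  std::vector<std::pair<int, R_xlen_t>> seeds;
  for (R_xlen_t i = 0; i < n; ++i)
    if (markers[i] > 0 && mask[i]) seeds.push_back({markers[i], i});
  std::sort(seeds.begin(), seeds.end());
  for (auto& s : seeds) pq.push({height[s.second], seq++, s.first, s.second});

  while (!pq.empty()) {
    FloodNode nd = pq.top();
    pq.pop();
    if (out[nd.idx] != 0) continue;
    out[nd.idx] = nd.id;
    int x = (int)(nd.idx / ((R_xlen_t)nz * ny));
    int rem = (int)(nd.idx % ((R_xlen_t)nz * ny));
    int y = rem / nz, z = rem % nz;
    for (auto& o : offs) {
      int zz = z + o[0], yy = y + o[1], xx = x + o[2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t idx = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (mask[idx] && out[idx] == 0)
        pq.push({height[idx], seq++, nd.id, idx});
    }
  }
  return out;
}

// Max filter over a 3x3x3 Chebyshev window (used for distance-peak markers).
// [[Rcpp::export(name = ".maxfilter3_cpp")]]
NumericVector maxfilter3_cpp(NumericVector x, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector out((R_xlen_t)nz * ny * nx);
  for (int xx = 0; xx < nx; ++xx)
    for (int yy = 0; yy < ny; ++yy)
      for (int zz = 0; zz < nz; ++zz) {
        double m = -HUGE_VAL;
        for (int dz = -1; dz <= 1; ++dz) {
          int z2 = zz + dz;
          if (z2 < 0 || z2 >= nz) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int y2 = yy + dy;
            if (y2 < 0 || y2 >= ny) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              int x2 = xx + dx;
              if (x2 < 0 || x2 >= nx) continue;
              double v = x[z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2)];
              if (v > m) m = v;
            }
          }
        }
        out[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)] = m;
      }
  return out;
}
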