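#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Arrays are R arrays with dim c(nx, ny, nz); linear index x + nx*(y + ny*z), 0-based.

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Rasterize a set of capsules (tube segments with hemispherical caps) into a
// binary volume. Segment endpoints and radii are in micrometres; sx/sy/sz are
// the voxel pitches. A voxel is set when its centre lies within `r` of the
// segment (centre-of-voxel inclusion).
// [[Rcpp::export]]
LogicalVector cpp_rasterize_tubes(int nx, int ny, int nz,
                                  double sx, double sy, double sz,
                                  NumericMatrix segs) {
  LogicalVector out(nx * ny * nz);
  for (int s = 0; s < segs.nrow(); ++s) {
    double x1 = segs(s, 0), y1 = segs(s, 1), z1 = segs(s, 2);
    double x2 = segs(s, 3), y2 = segs(s, 4), z2 = segs(s, 5);
    double r  = segs(s, 6);
    if (r <= 0) continue;
    double lox = std::min(x1, x2) - r, hix = std::max(x1, x2) + r;
    double loy = std::min(y1, y2) - r, hiy = std::max(y1, y2) + r;
    double loz = std::min(z1, z2) - r, hiz = std::max(z1, z2) + r;
    int ix0 = std::max(0, (int)std::floor(lox / sx - 0.5));
    int ix1 = std::min(nx - 1, (int)std::ceil(hix / sx - 0.5));
    int iy0 = std::max(0, (int)std::floor(loy / sy - 0.5));
    int iy1 = std::min(ny - 1, (int)std::ceil(hiy / sy - 0.5));
    int iz0 = std::max(0, (int)std::floor(loz / sz - 0.5));
    int iz1 = std::min(nz - 1, (int)std::ceil(hiz / sz - 0.5));
    double dx = x2 - x1, dy = y2 - y1, dz = z2 - z1;
    double len2 = dx * dx + dy * dy + dz * dz;
    double r2 = r * r;
    for (int z = iz0; z <= iz1; ++z) {
      double cz = (z + 0.5) * sz;
      for (int y = iy0; y <= iy1; ++y) {
        double cy = (y + 0.5) * sy;
        for (int x = ix0; x <= ix1; ++x) {
          double cx = (x + 0.5) * sx;
          double t = 0.0;
          if (len2 > 0) {
            t = ((cx - x1) * dx + (cy - y1) * dy + (cz - z1) * dz) / len2;
            if (t < 0) t = 0; else if (t > 1) t = 1;
          }
          double qx = x1 + t * dx - cx, qy = y1 + t * dy - cy, qz = z1 + t * dz - cz;
          if (qx * qx + qy * qy + qz * qz <= r2)
            out[lin(x, y, z, nx, ny)] = true;
        }
      }
    }
    // guarantee a connected centreline even when the tube is thinner than
    // the voxel pitch: mark the voxel nearest to densely sampled axis points
    double len = std::sqrt(len2);
    double step = 0.5 * std::min(sx, std::min(sy, sz));
    int nstep = std::max(1, (int)std::ceil(len / step));
    for (int k = 0; k <= nstep; ++k) {
      double t = (double)k / nstep;
      double px = x1 + t * dx, py = y1 + t * dy, pz = z1 + t * dz;
      int vx = (int)std::floor(px / sx);
      int vy = (int)std::floor(py / sy);
      int vz = (int)std::floor(pz / sz);
      if (vx >= 0 && vx < nx && vy >= 0 && vy < ny && vz >= 0 && vz < nz)
        out[lin(vx, vy, vz, nx, ny)] = true;
    }
  }
  return out;
}

// Connected-component labelling of a 3D binary volume (connectivity 6 or 26).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  IntegerVector lab(n);
  std::vector<int> stack;
  int cur = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++cur;
    stack.clear();
    stack.push_back(i);
    lab[i] = cur;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
              continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            int w = lin(xx, yy, zz, nx, ny);
            if (mask[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
          }
    }
  }
  return lab;
}

// Chamfer (weighted two-pass) distance transform: distance in micrometres from
// each foreground voxel to the nearest background voxel; voxels outside the
// volume count as background.
// [[Rcpp::export]]
NumericVector cpp_chamfer_dt(LogicalVector mask, IntegerVector dim,
                             double sx, double sy, double sz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  const double INF = 1e30;
  NumericVector d(n);
  for (int i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0.0;
  // 13 "causal" offsets (half of the 26-neighbourhood)
  int off[13][3] = {
    {-1, 0, 0}, {0, -1, 0}, {0, 0, -1}, {-1, -1, 0}, {-1, 1, 0},
    {-1, 0, -1}, {-1, 0, 1}, {0, -1, -1}, {0, -1, 1}, {-1, -1, -1},
    {-1, -1, 1}, {-1, 1, -1}, {-1, 1, 1}};
  double w[13];
  for (int k = 0; k < 13; ++k) {
    double ex = off[k][0] * sx, ey = off[k][1] * sy, ez = off[k][2] * sz;
    w[k] = std::sqrt(ex * ex + ey * ey + ez * ez);
  }
  double sm = std::min(sx, std::min(sy, sz));
  // forward
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = lin(x, y, z, nx, ny);
        if (d[i] == 0.0) continue;
        double best = d[i];
        if (x == 0 || x == nx - 1 || y == 0 || y == ny - 1 || z == 0 || z == nz - 1)
          best = std::min(best, sm);
        for (int k = 0; k < 13; ++k) {
          int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          best = std::min(best, d[lin(xx, yy, zz, nx, ny)] + w[k]);
        }
        d[i] = best;
      }
  // backward
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) {
        int i = lin(x, y, z, nx, ny);
        if (d[i] == 0.0) continue;
        double best = d[i];
        for (int k = 0; k < 13; ++k) {
          int xx = x - off[k][0], yy = y - off[k][1], zz = z - off[k][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          best = std::min(best, d[lin(xx, yy, zz, nx, ny)] + w[k]);
        }
        d[i] = best;
      }
  return d;
}

// ---- simple-point machinery for homotopic thinning -------------------------

// Gather the 3x3x3 neighbourhood of voxel v as 27 booleans (centre index 13);
// out-of-volume positions are background.
static void neighborhood27(const std::vector<char> &img, int x, int y, int z,
                           int nx, int ny, int nz, bool nb[27]) {
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          nb[k] = false;
        else
          nb[k] = img[lin(xx, yy, zz, nx, ny)] != 0;
      }
}

static inline void pos3(int k, int &dx, int &dy, int &dz) {
  dx = k % 3 - 1; dy = (k / 3) % 3 - 1; dz = k / 9 - 1;
}

// A voxel is simple (its deletion preserves topology) iff
//  (a) the foreground of its 26-neighbourhood is one 26-connected component, and
//  (b) the background of its 18-neighbourhood is one 6-connected component
//      that is 6-adjacent to the centre.
static bool is_simple(const bool nb[27]) {
  // (a) foreground 26-components among the 26 neighbours
  bool seen[27] = {false};
  int ncomp = 0, nfg = 0;
  for (int k = 0; k < 27; ++k) if (k != 13 && nb[k]) ++nfg;
  if (nfg == 0) return false;  // isolated point: deletion removes a component
  for (int k = 0; k < 27; ++k) {
    if (k == 13 || !nb[k] || seen[k]) continue;
    if (++ncomp > 1) return false;
    // BFS over 26-adjacency within the neighbourhood
    std::vector<int> st(1, k);
    seen[k] = true;
    while (!st.empty()) {
      int v = st.back(); st.pop_back();
      int vx, vy, vz; pos3(v, vx, vy, vz);
      for (int u = 0; u < 27; ++u) {
        if (u == 13 || !nb[u] || seen[u]) continue;
        int ux, uy, uz; pos3(u, ux, uy, uz);
        if (std::abs(ux - vx) <= 1 && std::abs(uy - vy) <= 1 && std::abs(uz - vz) <= 1) {
          seen[u] = true; st.push_back(u);
        }
      }
    }
  }
  if (ncomp != 1) return false;
  // (b) background 6-components in the 18-neighbourhood touching a face neighbour
  bool seenb[27] = {false};
  int nbg = 0;
  for (int k = 0; k < 27; ++k) {
    int kx, ky, kz; pos3(k, kx, ky, kz);
    int manh = std::abs(kx) + std::abs(ky) + std::abs(kz);
    if (k == 13 || manh > 2 || nb[k] || seenb[k]) continue;
    if (manh != 1) continue;  // start components only from face neighbours
    ++nbg;
    if (nbg > 1) return false;
    std::vector<int> st(1, k);
    seenb[k] = true;
    while (!st.empty()) {
      int v = st.back(); st.pop_back();
      int vx, vy, vz; pos3(v, vx, vy, vz);
      for (int u = 0; u < 27; ++u) {
        int ux, uy, uz; pos3(u, ux, uy, uz);
        int m = std::abs(ux) + std::abs(uy) + std::abs(uz);
        if (u == 13 || m > 2 || nb[u] || seenb[u]) continue;
        if (std::abs(ux - vx) + std::abs(uy - vy) + std::abs(uz - vz) == 1) {
          seenb[u] = true; st.push_back(u);
        }
      }
    }
  }
  return nbg == 1;
}

struct QItem {
  double d; int idx;
  bool operator<(const QItem &o) const {  // min-heap via priority_queue
    if (d != o.d) return d > o.d;
    return idx > o.idx;
  }
};

// Distance-ordered homotopic thinning to a 1-voxel-wide skeleton. Voxels are
// deleted in order of increasing distance-to-background provided they are
// simple points and not curve endpoints (<= 1 foreground 26-neighbour).
// Assumes an isotropic grid.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<char> img(n);
  for (int i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;
  NumericVector dt = cpp_chamfer_dt(mask, dim, 1.0, 1.0, 1.0);
  std::priority_queue<QItem> pq;
  for (int i = 0; i < n; ++i)
    if (img[i] && dt[i] <= 1.0) pq.push({dt[i], i});
  bool nb[27];
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    int i = it.idx;
    if (!img[i]) continue;
    int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    neighborhood27(img, x, y, z, nx, ny, nz, nb);
    int cnt = 0;
    for (int k = 0; k < 27; ++k) if (k != 13 && nb[k]) ++cnt;
    if (cnt <= 1) continue;            // endpoint: preserve
    if (!is_simple(nb)) continue;
    img[i] = 0;
    for (int k = 0; k < 27; ++k) {
      if (k == 13 || !nb[k]) continue;
      int dx, dy, dz; pos3(k, dx, dy, dz);
      int w = lin(x + dx, y + dy, z + dz, nx, ny);
      if (img[w]) pq.push({dt[w], w});
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = img[i] != 0;
  return out;
}
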