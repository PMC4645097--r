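// Low-level voxel operations on 3D grids stored as R arrays
// (column-major: linear index = i + nx*(j + ny*k), all indices 0-based here).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double INF = 1e20;

static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// distances in voxel units to the nearest TRUE voxel. All-false input -> INF.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t t = 0; t < n; t++) out[t] = (mask[t] == TRUE) ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = lin(0, j, k, nx, ny);
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, d, nx, v, z);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      for (int j = 0; j < ny; j++) f[j] = out[lin(i, j, k, nx, ny)];
      dt1d(f, d, ny, v, z);
      for (int j = 0; j < ny; j++) out[lin(i, j, k, nx, ny)] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      for (int k = 0; k < nz; k++) f[k] = out[lin(i, j, k, nx, ny)];
      dt1d(f, d, nz, v, z);
      for (int k = 0; k < nz; k++) out[lin(i, j, k, nx, ny)] = d[k];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling, connectivity 6 / 18 / 26.
// Labels are assigned in column-major scan order starting at 1.
// ---------------------------------------------------------------------------

static int neighbor_offsets(int connectivity, int offs[26][3]) {
  int m = 0;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        offs[m][0] = dx; offs[m][1] = dy; offs[m][2] = dz;
        m++;
      }
  return m;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);  // zero-initialised
  int offs[26][3];
  int m = neighbor_offsets(connectivity, offs);

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (mask[s] != TRUE || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int t = 0; t < m; t++) {
        int ii = i + offs[t][0], jj = j + offs[t][1], kk = k + offs[t][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t q = lin(ii, jj, kk, nx, ny);
        if (mask[q] == TRUE && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Local mean threshold via an integral image; window is a cube of half-width
// r, truncated at volume borders. On iff value > local mean + offset.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_local_threshold(NumericVector vol, IntegerVector dim,
                                  int r, double offset) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t np = (R_xlen_t)(nx + 1) * (ny + 1) * (nz + 1);
  std::vector<double> S(np, 0.0);
  R_xlen_t px = nx + 1, py = ny + 1;
  auto plin = [&](int i, int j, int k) {
    return (R_xlen_t)i + px * ((R_xlen_t)j + py * k);
  };
  for (int k = 1; k <= nz; k++)
    for (int j = 1; j <= ny; j++)
      for (int i = 1; i <= nx; i++) {
        S[plin(i, j, k)] = vol[lin(i - 1, j - 1, k - 1, nx, ny)]
          + S[plin(i - 1, j, k)] + S[plin(i, j - 1, k)] + S[plin(i, j, k - 1)]
          - S[plin(i - 1, j - 1, k)] - S[plin(i - 1, j, k - 1)]
          - S[plin(i, j - 1, k - 1)] + S[plin(i - 1, j - 1, k - 1)];
      }
  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; k++) {
    int k0 = std::max(0, k - r), k1 = std::min(nz - 1, k + r);
    for (int j = 0; j < ny; j++) {
      int j0 = std::max(0, j - r), j1 = std::min(ny - 1, j + r);
      for (int i = 0; i < nx; i++) {
        int i0 = std::max(0, i - r), i1 = std::min(nx - 1, i + r);
        double sum = S[plin(i1 + 1, j1 + 1, k1 + 1)]
          - S[plin(i0, j1 + 1, k1 + 1)] - S[plin(i1 + 1, j0, k1 + 1)]
          - S[plin(i1 + 1, j1 + 1, k0)] + S[plin(i0, j0, k1 + 1)]
          + S[plin(i0, j1 + 1, k0)] + S[plin(i1 + 1, j0, k0)]
          - S[plin(i0, j0, k0)];
        double cnt = (double)(i1 - i0 + 1) * (j1 - j0 + 1) * (k1 - k0 + 1);
        double v = vol[lin(i, j, k, nx, ny)];
        out[lin(i, j, k, nx, ny)] = (v > sum / cnt + offset) ? TRUE : FALSE;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// One sweep of insideness-based lumen filling. For each candidate background
// voxel, rays are marched along a fixed direction set; a ray scores a hit if
// it meets an on-voxel within max_r (voxel units). Returns the 1-based linear
// indices of voxels whose hit fraction reaches inside_fraction.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_inside_candidates(LogicalVector mask, IntegerVector dim,
                                    IntegerVector cand, NumericMatrix dirs,
                                    double max_r, double inside_fraction,
                                    double step) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nd = dirs.nrow();
  int allowed_miss = (int)std::floor(nd * (1.0 - inside_fraction) + 1e-9);
  std::vector<int> keep;
  int nstep = (int)std::ceil(max_r / step);
  for (R_xlen_t c = 0; c < cand.size(); c++) {
    R_xlen_t s = (R_xlen_t)cand[c] - 1;
    int i = (int)(s % nx);
    int j = (int)((s / nx) % ny);
    int k = (int)(s / ((R_xlen_t)nx * ny));
    int miss = 0, hit = 0;
    for (int d = 0; d < nd && miss <= allowed_miss; d++) {
      double ux = dirs(d, 0), uy = dirs(d, 1), uz = dirs(d, 2);
      bool got = false;
      for (int t = 1; t <= nstep; t++) {
        double r = t * step;
        if (r > max_r) break;
        int ii = (int)std::lround(i + r * ux);
        int jj = (int)std::lround(j + r * uy);
        int kk = (int)std::lround(k + r * uz);
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          break;  // left the volume: counts as a miss
        if (mask[lin(ii, jj, kk, nx, ny)] == TRUE) { got = true; break; }
      }
      if (got) hit++; else miss++;
    }
    if (miss <= allowed_miss && (double)hit / nd >= inside_fraction)
      keep.push_back((int)(s + 1));
  }
  return wrap(keep);
}

// ---------------------------------------------------------------------------
// Topology-preserving 3D thinning to a one-voxel-wide centerline skeleton.
// A voxel is deleted only when it is a simple point for (26,6) connectivity
// (one 26-component of foreground in N26, one 6-component of background in
// N18 that is 6-adjacent to the center) and not a curve endpoint. Deletion
// proceeds in six directional subiterations (U,D,N,S,E,W) with sequential
// re-checking, so the result is deterministic.
// ---------------------------------------------------------------------------

namespace {

struct ThinCtx {
  std::vector<uint8_t> img;
  int nx, ny, nz;
  inline uint8_t at(int i, int j, int k) const {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0;
    return img[lin(i, j, k, nx, ny)];
  }
};

// local 3x3x3 cube index: c = x + 3*(y + 3*z), x,y,z in 0..2, center = 13
inline int cube_idx(int x, int y, int z) { return x + 3 * (y + 3 * z); }

bool is_simple(const ThinCtx& C, int i, int j, int k) {
  uint8_t nb[27];
  int nfg = 0;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int c = cube_idx(dx + 1, dy + 1, dz + 1);
        if (dx == 0 && dy == 0 && dz == 0) { nb[c] = 0; continue; }
        nb[c] = C.at(i + dx, j + dy, k + dz);
        if (nb[c]) nfg++;
      }
  if (nfg == 0) return false;

  // Condition A: exactly one 26-connected foreground component in N26.
  {
    int seen[27] = {0};
    int ncomp = 0;
    for (int c0 = 0; c0 < 27; c0++) {
      if (c0 == 13 || !nb[c0] || seen[c0]) continue;
      ncomp++;
      if (ncomp > 1) return false;
      int stack[27], sp = 0;
      stack[sp++] = c0;
      seen[c0] = 1;
      while (sp) {
        int c = stack[--sp];
        int x = c % 3, y = (c / 3) % 3, z = c / 9;
        for (int dz = -1; dz <= 1; dz++)
          for (int dy = -1; dy <= 1; dy++)
            for (int dx = -1; dx <= 1; dx++) {
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || y2 < 0 || z2 < 0 || x2 > 2 || y2 > 2 || z2 > 2)
                continue;
              int c2 = cube_idx(x2, y2, z2);
              if (c2 == 13 || c2 == c || !nb[c2] || seen[c2]) continue;
              seen[c2] = 1;
              stack[sp++] = c2;
            }
      }
    }
    if (ncomp != 1) return false;
  }

  // Condition B: exactly one 6-connected background component in N18 that is
  // 6-adjacent to the center.
  {
    bool in18[27];
    for (int c = 0; c < 27; c++) {
      int x = c % 3 - 1, y = (c / 3) % 3 - 1, z = c / 9 - 1;
      int manh = std::abs(x) + std::abs(y) + std::abs(z);
      in18[c] = (manh == 1 || manh == 2);
    }
    int seen[27] = {0};
    int ncomp = 0;
    for (int c0 = 0; c0 < 27; c0++) {
      if (!in18[c0] || nb[c0] || seen[c0]) continue;
      // grow the 6-connected background component within N18
      int stack[27], sp = 0;
      stack[sp++] = c0;
      seen[c0] = 1;
      bool touches_center = false;
      while (sp) {
        int c = stack[--sp];
        int x = c % 3, y = (c / 3) % 3, z = c / 9;
        int manh = std::abs(x - 1) + std::abs(y - 1) + std::abs(z - 1);
        if (manh == 1) touches_center = true;
        const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
        for (int t = 0; t < 6; t++) {
          int x2 = x + d6[t][0], y2 = y + d6[t][1], z2 = z + d6[t][2];
          if (x2 < 0 || y2 < 0 || z2 < 0 || x2 > 2 || y2 > 2 || z2 > 2) continue;
          int c2 = cube_idx(x2, y2, z2);
          if (!in18[c2] || nb[c2] || seen[c2]) continue;
          seen[c2] = 1;
          stack[sp++] = c2;
        }
      }
      if (touches_center) {
        ncomp++;
        if (ncomp > 1) return false;
      }
    }
    if (ncomp != 1) return false;
  }
  return true;
}

inline int count_fg26(const ThinCtx& C, int i, int j, int k) {
  int n = 0;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (!dx && !dy && !dz) continue;
        if (C.at(i + dx, j + dy, k + dz)) n++;
      }
  return n;
}

}  // namespace

// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, IntegerVector dim) {
  ThinCtx C;
  C.nx = dim[0]; C.ny = dim[1]; C.nz = dim[2];
  R_xlen_t n = (R_xlen_t)C.nx * C.ny * C.nz;
  C.img.assign(n, 0);
  std::vector<R_xlen_t> fg;
  for (R_xlen_t t = 0; t < n; t++)
    if (mask[t] == TRUE) { C.img[t] = 1; fg.push_back(t); }

  const int dirs6[6][3] = {{0,0,1},{0,0,-1},{0,1,0},{0,-1,0},{1,0,0},{-1,0,0}};
  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; d++) {
      cand.clear();
      for (size_t t = 0; t < fg.size(); t++) {
        R_xlen_t s = fg[t];
        if (!C.img[s]) continue;
        int i = (int)(s % C.nx);
        int j = (int)((s / C.nx) % C.ny);
        int k = (int)(s / ((R_xlen_t)C.nx * C.ny));
        if (C.at(i + dirs6[d][0], j + dirs6[d][1], k + dirs6[d][2])) continue;
        int nn = count_fg26(C, i, j, k);
        if (nn <= 1) continue;  // endpoint or isolated voxel
        if (is_simple(C, i, j, k)) cand.push_back(s);
      }
      for (size_t t = 0; t < cand.size(); t++) {
        R_xlen_t s = cand[t];
        int i = (int)(s % C.nx);
        int j = (int)((s / C.nx) % C.ny);
        int k = (int)(s / ((R_xlen_t)C.nx * C.ny));
        if (count_fg26(C, i, j, k) <= 1) continue;
        if (!is_simple(C, i, j, k)) continue;
        C.img[s] = 0;
        changed = true;
      }
    }
    // compact the foreground list every cycle
    std::vector<R_xlen_t> keep;
    keep.reserve(fg.size());
    for (size_t t = 0; t < fg.size(); t++)
      if (C.img[fg[t]]) keep.push_back(fg[t]);
    fg.swap(keep);
  }

  LogicalVector out(n);
  for (R_xlen_t t = 0; t < n; t++) out[t] = C.img[t] ? TRUE : FALSE;
  return out;
}

// ---------------------------------------------------------------------------
// Capsule-union rasteriser. segs columns: x1,y1,z1,x2,y2,z2,r (world units,
// i.e. micrometres). Voxel (i,j,k) center sits at origin + vs*(i,j,k).
// Returns 0 = outside, 1 = inside union of capsules ("solid"),
// 2 = additionally inside the union of capsules shrunk by wall ("interior").
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_rasterize_capsules(IntegerVector dim, double vs,
                                     NumericVector origin, NumericMatrix segs,
                                     double wall) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n);
  for (int s = 0; s < segs.nrow(); s++) {
    double ax = segs(s, 0), ay = segs(s, 1), az = segs(s, 2);
    double bx = segs(s, 3), by = segs(s, 4), bz = segs(s, 5);
    double r = segs(s, 6);
    double ri = (wall > 0) ? std::max(0.0, r - wall) : -1.0;
    double vx = bx - ax, vy = by - ay, vz = bz - az;
    double vv = vx * vx + vy * vy + vz * vz;
    double lo[3], hi[3];
    lo[0] = std::min(ax, bx) - r; hi[0] = std::max(ax, bx) + r;
    lo[1] = std::min(ay, by) - r; hi[1] = std::max(ay, by) + r;
    lo[2] = std::min(az, bz) - r; hi[2] = std::max(az, bz) + r;
    int i0 = std::max(0, (int)std::floor((lo[0] - origin[0]) / vs));
    int i1 = std::min(nx - 1, (int)std::ceil((hi[0] - origin[0]) / vs));
    int j0 = std::max(0, (int)std::floor((lo[1] - origin[1]) / vs));
    int j1 = std::min(ny - 1, (int)std::ceil((hi[1] - origin[1]) / vs));
    int k0 = std::max(0, (int)std::floor((lo[2] - origin[2]) / vs));
    int k1 = std::min(nz - 1, (int)std::ceil((hi[2] - origin[2]) / vs));
    double r2 = r * r, ri2 = ri * ri;
    for (int k = k0; k <= k1; k++)
      for (int j = j0; j <= j1; j++)
        for (int i = i0; i <= i1; i++) {
          double px = origin[0] + vs * i - ax;
          double py = origin[1] + vs * j - ay;
          double pz = origin[2] + vs * k - az;
          double t = (vv > 0) ? (px * vx + py * vy + pz * vz) / vv : 0.0;
          if (t < 0) t = 0; else if (t > 1) t = 1;
          double dx = px - t * vx, dy = py - t * vy, dz = pz - t * vz;
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 <= r2) {
            R_xlen_t q = lin(i, j, k, nx, ny);
            if (ri >= 0 && d2 <= ri2) out[q] = 2;
            else if (out[q] == 0) out[q] = 1;
          }
        }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Lattice-exact insideness for the 26 voxel-neighbour directions: for every
// voxel, counts along how many of the 26 directions an on-voxel occurs
// within max_r (voxel units). One linear sweep per direction.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_inside_counts26(LogicalVector mask, IntegerVector dim,
                                  double max_r) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<uint16_t> steps(n);
  IntegerVector counts(n);  // zero-initialised
  const uint16_t FAR = 65535;

  int offs[26][3];
  neighbor_offsets(26, offs);
  for (int d = 0; d < 26; d++) {
    int dx = offs[d][0], dy = offs[d][1], dz = offs[d][2];
    double len = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
    uint16_t maxstep16 = (uint16_t)std::min(65534.0, std::floor(max_r / len));
    // iterate so that v+d is visited before v
    int i0 = dx > 0 ? nx - 1 : 0, i1 = dx > 0 ? -1 : nx, is = dx > 0 ? -1 : 1;
    int j0 = dy > 0 ? ny - 1 : 0, j1 = dy > 0 ? -1 : ny, js = dy > 0 ? -1 : 1;
    int k0 = dz > 0 ? nz - 1 : 0, k1 = dz > 0 ? -1 : nz, ks = dz > 0 ? -1 : 1;
    for (int k = k0; k != k1; k += ks)
      for (int j = j0; j != j1; j += js)
        for (int i = i0; i != i1; i += is) {
          R_xlen_t v = lin(i, j, k, nx, ny);
          if (mask[v] == TRUE) { steps[v] = 0; continue; }
          int ii = i + dx, jj = j + dy, kk = k + dz;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) {
            steps[v] = FAR;
            continue;
          }
          uint16_t s = steps[lin(ii, jj, kk, nx, ny)];
          steps[v] = (s >= FAR - 1) ? FAR : (uint16_t)(s + 1);
        }
    for (R_xlen_t v = 0; v < n; v++)
      if (mask[v] != TRUE && steps[v] <= maxstep16) counts[v]++;
  }
  return counts;
}
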