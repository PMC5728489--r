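#include <Rcpp.h>
#include <vector>
#include <array>
#include <deque>
#include <set>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Column-major voxel indexing: idx = x + nx * (y + ny * z), 0-based.

static inline int vidx(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + (long long)ny * z);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher, separable
// lower-envelope-of-parabolas scheme). Distance from each nonzero voxel to
// the nearest zero voxel center; 0 on zero voxels. Exact.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& zbuf) {
  int k = 0;
  v[0] = 0;
  zbuf[0] = -std::numeric_limits<double>::infinity();
  zbuf[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= zbuf[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt")]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e30;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> d2(n);
  for (R_xlen_t i = 0; i < n; ++i) d2[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  if (nx > 1) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) f[x] = d2[vidx(x, y, z, nx, ny)];
        dt1d(f, d, nx, v, zbuf);
        for (int x = 0; x < nx; ++x) d2[vidx(x, y, z, nx, ny)] = d[x];
      }
  }
  // y pass
  if (ny > 1) {
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y) f[y] = d2[vidx(x, y, z, nx, ny)];
        dt1d(f, d, ny, v, zbuf);
        for (int y = 0; y < ny; ++y) d2[vidx(x, y, z, nx, ny)] = d[y];
      }
  }
  // z pass
  if (nz > 1) {
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        for (int z = 0; z < nz; ++z) f[z] = d2[vidx(x, y, z, nx, ny)];
        dt1d(f, d, nz, v, zbuf);
        for (int z = 0; z < nz; ++z) d2[vidx(x, y, z, nx, ny)] = d[z];
      }
  }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = mask[i] ? std::sqrt(d2[i]) : 0.0;
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (6 or 26 connectivity), BFS in raster order:
// labels are dense 1..L and deterministic.
// ---------------------------------------------------------------------------

static void neighbor_offsets(int conn, int nx, int ny,
                             std::vector<std::array<int, 3>>& offs) {
  offs.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (conn == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }
}

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> offs;
  neighbor_offsets(connectivity, nx, ny, offs);

  int next = 0;
  std::vector<int> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back((int)i);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int cz = cur / (nx * ny);
      int rem = cur - cz * nx * ny;
      int cy = rem / nx;
      int cx = rem - cy * nx;
      for (auto& o : offs) {
        int x = cx + o[0], y = cy + o[1], z = cz + o[2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        int j = vidx(x, y, z, nx, ny);
        if (mask[j] && !lab[j]) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Ray casting. Rays are traversed voxel-by-voxel with a Bresenham-style
// dominant-axis march: the axis with the largest |direction| component
// advances one voxel per step, the others accumulate fractional offsets and
// are rounded to the nearest voxel. The hit is the first background voxel
// center; distance is measured center-to-center.
// ---------------------------------------------------------------------------

struct Hit {
  bool hit;
  double px, py, pz; // hit voxel center
  double dist;
};

static Hit cast_ray(const int* mask, int nx, int ny, int nz,
                    double x0, double y0, double z0,
                    double dx, double dy, double dz, double cap) {
  Hit h;
  h.hit = false;
  h.dist = cap;
  double ax = std::fabs(dx), ay = std::fabs(dy), az = std::fabs(dz);
  double amax = std::max(ax, std::max(ay, az));
  if (amax <= 0) return h;
  double sx = dx / amax, sy = dy / amax, sz = dz / amax;
  double steplen = std::sqrt(sx * sx + sy * sy + sz * sz);
  int kmax = (int)std::floor(cap / steplen);
  for (int k = 1; k <= kmax; ++k) {
    double px = x0 + k * sx, py = y0 + k * sy, pz = z0 + k * sz;
    int ix = (int)std::lround(px);
    int iy = (int)std::lround(py);
    int iz = (int)std::lround(pz);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
      return h; // left the grid without meeting background
    if (!mask[vidx(ix, iy, iz, nx, ny)]) {
      double ddx = ix - x0, ddy = iy - y0, ddz = iz - z0;
      h.hit = true;
      h.px = ix; h.py = iy; h.pz = iz;
      h.dist = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      return h;
    }
  }
  return h;
}

// Jacobi eigendecomposition of a symmetric 3x3 matrix; deterministic sweep
// order, so degenerate (isotropic) inputs always resolve the same way.
static void eig3_sym(double a[3][3], double eval[3], double evec[3][3]) {
  double v[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  double m[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) m[i][j] = a[i][j];
  for (int sweep = 0; sweep < 64; ++sweep) {
    double off = std::fabs(m[0][1]) + std::fabs(m[0][2]) + std::fabs(m[1][2]);
    if (off < 1e-14) break;
    const int pairs[3][2] = {{0, 1}, {0, 2}, {1, 2}};
    for (int pi = 0; pi < 3; ++pi) {
      int p = pairs[pi][0], q = pairs[pi][1];
      if (std::fabs(m[p][q]) < 1e-300) continue;
      double theta = (m[q][q] - m[p][p]) / (2.0 * m[p][q]);
      double t = (theta >= 0 ? 1.0 : -1.0) /
                 (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
      double c = 1.0 / std::sqrt(t * t + 1.0);
      double s = t * c;
      for (int k = 0; k < 3; ++k) {
        double mkp = m[k][p], mkq = m[k][q];
        m[k][p] = c * mkp - s * mkq;
        m[k][q] = s * mkp + c * mkq;
      }
      for (int k = 0; k < 3; ++k) {
        double mpk = m[p][k], mqk = m[q][k];
        m[p][k] = c * mpk - s * mqk;
        m[q][k] = s * mpk + c * mqk;
      }
      for (int k = 0; k < 3; ++k) {
        double vkp = v[k][p], vkq = v[k][q];
        v[k][p] = c * vkp - s * vkq;
        v[k][q] = s * vkp + c * vkq;
      }
    }
  }
  for (int i = 0; i < 3; ++i) {
    eval[i] = m[i][i];
    for (int k = 0; k < 3; ++k) evec[k][i] = v[k][i];
  }
}

// Least-squares plane normal of a point cloud: eigenvector of the scatter
// matrix with the smallest eigenvalue, sign fixed so the largest-magnitude
// component is positive (ties: first such component).
static bool scatter_normal(const std::vector<double>& px,
                           const std::vector<double>& py,
                           const std::vector<double>& pz, double normal[3]) {
  size_t np = px.size();
  if (np < 3) return false;
  double cx = 0, cy = 0, cz = 0;
  for (size_t i = 0; i < np; ++i) { cx += px[i]; cy += py[i]; cz += pz[i]; }
  cx /= np; cy /= np; cz /= np;
  double a[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  for (size_t i = 0; i < np; ++i) {
    double dx = px[i] - cx, dy = py[i] - cy, dz = pz[i] - cz;
    a[0][0] += dx * dx; a[0][1] += dx * dy; a[0][2] += dx * dz;
    a[1][1] += dy * dy; a[1][2] += dy * dz; a[2][2] += dz * dz;
  }
  a[1][0] = a[0][1]; a[2][0] = a[0][2]; a[2][1] = a[1][2];
  double eval[3], evec[3][3];
  eig3_sym(a, eval, evec);
  int imin = 0;
  for (int i = 1; i < 3; ++i) if (eval[i] < eval[imin]) imin = i;
  double nrm[3] = {evec[0][imin], evec[1][imin], evec[2][imin]};
  double len = std::sqrt(nrm[0] * nrm[0] + nrm[1] * nrm[1] + nrm[2] * nrm[2]);
  if (len <= 0) return false;
  for (int i = 0; i < 3; ++i) nrm[i] /= len;
  int ibig = 0;
  for (int i = 1; i < 3; ++i)
    if (std::fabs(nrm[i]) > std::fabs(nrm[ibig])) ibig = i;
  if (nrm[ibig] < 0) for (int i = 0; i < 3; ++i) nrm[i] = -nrm[i];
  for (int i = 0; i < 3; ++i) normal[i] = nrm[i];
  return true;
}

// In-plane orthonormal basis from a unit normal: cross the normal with the
// coordinate axis of its smallest-magnitude component (ties: smallest index).
static void plane_basis(const double normal[3], double u[3], double w[3]) {
  int imin = 0;
  for (int i = 1; i < 3; ++i)
    if (std::fabs(normal[i]) < std::fabs(normal[imin])) imin = i;
  double e[3] = {0, 0, 0};
  e[imin] = 1.0;
  // u = normalize(normal x e)
  u[0] = normal[1] * e[2] - normal[2] * e[1];
  u[1] = normal[2] * e[0] - normal[0] * e[2];
  u[2] = normal[0] * e[1] - normal[1] * e[0];
  double lu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  for (int i = 0; i < 3; ++i) u[i] /= lu;
  // w = normal x u (unit by construction)
  w[0] = normal[1] * u[2] - normal[2] * u[1];
  w[1] = normal[2] * u[0] - normal[0] * u[2];
  w[2] = normal[0] * u[1] - normal[1] * u[0];
}

// [[Rcpp::export(name = ".cpp_fit_plane")]]
List cpp_fit_plane(IntegerVector mask, IntegerVector dims, IntegerVector x0,
                   NumericMatrix dirs, double cap) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int* mk = INTEGER(mask);
  std::vector<double> px, py, pz;
  int n = dirs.nrow();
  for (int i = 0; i < n; ++i) {
    Hit h = cast_ray(mk, nx, ny, nz, x0[0], x0[1], x0[2],
                     dirs(i, 0), dirs(i, 1), dirs(i, 2), cap);
    if (h.hit) { px.push_back(h.px); py.push_back(h.py); pz.push_back(h.pz); }
  }
  if (px.size() < 3)
    stop("plane fit failed: fewer than 3 background hit points (unbounded foreground region or ray cap too small)");
  double normal[3];
  if (!scatter_normal(px, py, pz, normal))
    stop("plane fit failed: degenerate hit-point scatter");
  NumericMatrix hits(px.size(), 3);
  for (size_t i = 0; i < px.size(); ++i) {
    hits(i, 0) = px[i]; hits(i, 1) = py[i]; hits(i, 2) = pz[i];
  }
  return List::create(_["normal"] = NumericVector::create(normal[0], normal[1], normal[2]),
                      _["n_hits"] = (int)px.size(),
                      _["hits"] = hits);
}

static double dist2d_at(const int* mk, int nx, int ny, int nz,
                        double x0, double y0, double z0,
                        const double normal[3], int m, double cap) {
  double u[3], w[3];
  plane_basis(normal, u, w);
  double best = cap;
  bool any = false;
  for (int j = 0; j < m; ++j) {
    double ang = 2.0 * M_PI * j / m;
    double ca = std::cos(ang), sa = std::sin(ang);
    double d[3] = {ca * u[0] + sa * w[0], ca * u[1] + sa * w[1],
                   ca * u[2] + sa * w[2]};
    Hit h = cast_ray(mk, nx, ny, nz, x0, y0, z0, d[0], d[1], d[2], cap);
    if (h.hit) {
      any = true;
      if (h.dist < best) best = h.dist;
    }
  }
  return any ? best : cap;
}

// [[Rcpp::export(name = ".cpp_distance2d_at")]]
double cpp_distance2d_at(IntegerVector mask, IntegerVector dims,
                         IntegerVector x0, NumericVector normal, int m,
                         double cap) {
  const double nn[3] = {normal[0], normal[1], normal[2]};
  return dist2d_at(INTEGER(mask), dims[0], dims[1], dims[2],
                   x0[0], x0[1], x0[2], nn, m, cap);
}

// [[Rcpp::export(name = ".cpp_distance_map_2d")]]
NumericVector cpp_distance_map_2d(IntegerVector mask, IntegerVector dims,
                                  NumericMatrix dirs3, int m, double cap) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int* mk = INTEGER(mask);
  int nd = dirs3.nrow();
  std::vector<double> dxs(nd), dys(nd), dzs(nd);
  for (int i = 0; i < nd; ++i) {
    dxs[i] = dirs3(i, 0); dys[i] = dirs3(i, 1); dzs[i] = dirs3(i, 2);
  }
  NumericVector out(n, 0.0);
  std::vector<double> px, py, pz;
  px.reserve(nd); py.reserve(nd); pz.reserve(nd);
  for (int z = 0; z < nz; ++z) {
    Rcpp::checkUserInterrupt();
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = vidx(x, y, z, nx, ny);
        if (!mk[i]) continue;
        px.clear(); py.clear(); pz.clear();
        for (int r = 0; r < nd; ++r) {
          Hit h = cast_ray(mk, nx, ny, nz, x, y, z, dxs[r], dys[r], dzs[r], cap);
          if (h.hit) { px.push_back(h.px); py.push_back(h.py); pz.push_back(h.pz); }
        }
        if (px.size() < 3)
          stop("2D distance map: fewer than 3 hit points at a foreground voxel; increase the ray cap");
        double normal[3];
        if (!scatter_normal(px, py, pz, normal))
          stop("2D distance map: degenerate plane fit");
        out[i] = dist2d_at(mk, nx, ny, nz, x, y, z, normal, m, cap);
      }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Hierarchical watershed flooding. Voxels are processed in ascending
// (value, index) order; minima plateaus become single basins; the first
// contact between two basins records a saddle event. Basins are NOT merged
// here -- merging is replayed later against persistence/size thresholds.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_watershed_hierarchy")]]
List cpp_watershed_hierarchy(NumericVector values, IntegerVector mask,
                             IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<std::array<int, 3>> offs;
  neighbor_offsets(26, nx, ny, offs);

  std::vector<int> fg;
  fg.reserve(n / 4);
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i]) fg.push_back((int)i);
  if (fg.empty()) stop("watershed: empty foreground mask");

  std::stable_sort(fg.begin(), fg.end(), [&](int a, int b) {
    if (values[a] != values[b]) return values[a] < values[b];
    return a < b;
  });

  std::vector<int> basin(n, 0);
  std::vector<double> basin_min;   // 1-based via index-1
  std::vector<int> basin_argmin;
  std::vector<double> ev_saddle;
  std::vector<int> ev_a, ev_b;
  std::set<std::pair<int, int>> seen;

  auto neighbors_of = [&](int cur, std::vector<int>& nb) {
    nb.clear();
    int cz = cur / (nx * ny);
    int rem = cur - cz * nx * ny;
    int cy = rem / nx;
    int cx = rem - cy * nx;
    for (auto& o : offs) {
      int x = cx + o[0], y = cy + o[1], z = cz + o[2];
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
      nb.push_back(vidx(x, y, z, nx, ny));
    }
  };

  auto record_events = [&](std::vector<int>& bset, double v) {
    std::sort(bset.begin(), bset.end());
    bset.erase(std::unique(bset.begin(), bset.end()), bset.end());
    for (size_t i = 0; i < bset.size(); ++i)
      for (size_t j = i + 1; j < bset.size(); ++j) {
        std::pair<int, int> key(bset[i], bset[j]);
        if (seen.insert(key).second) {
          ev_saddle.push_back(v);
          ev_a.push_back(bset[i]);
          ev_b.push_back(bset[j]);
        }
      }
  };

  std::vector<int> nb, bset;
  std::vector<char> queued(n, 0);
  size_t gstart = 0;
  const size_t nf = fg.size();
  while (gstart < nf) {
    double v = values[fg[gstart]];
    size_t gend = gstart;
    while (gend < nf && values[fg[gend]] == v) ++gend;

    // BFS from voxels adjacent to already-assigned (lower or earlier) voxels
    std::deque<int> q;
    for (size_t g = gstart; g < gend; ++g) {
      int cur = fg[g];
      neighbors_of(cur, nb);
      for (int j : nb)
        if (basin[j]) { q.push_back(cur); queued[cur] = 1; break; }
    }
    while (!q.empty()) {
      int cur = q.front();
      q.pop_front();
      if (basin[cur]) continue;
      neighbors_of(cur, nb);
      bset.clear();
      int chosen = 0;
      double chosen_min = std::numeric_limits<double>::infinity();
      for (int j : nb) {
        int b = basin[j];
        if (!b) continue;
        bset.push_back(b);
        double bm = basin_min[b - 1];
        if (bm < chosen_min || (bm == chosen_min && b < chosen)) {
          chosen = b;
          chosen_min = bm;
        }
      }
      basin[cur] = chosen;
      record_events(bset, v);
      for (int j : nb) {
        if (!basin[j] && mask[j] && !queued[j] && values[j] == v) {
          q.push_back(j);
          queued[j] = 1;
        }
      }
    }

    // Remaining unassigned voxels at this level are minima plateaus:
    // one basin per 26-connected component, seeded in index order.
    for (size_t g = gstart; g < gend; ++g) {
      int cur = fg[g];
      if (basin[cur]) continue;
      basin_min.push_back(v);
      basin_argmin.push_back(cur);
      int bid = (int)basin_min.size();
      std::vector<int> stack{cur};
      basin[cur] = bid;
      while (!stack.empty()) {
        int c2 = stack.back();
        stack.pop_back();
        neighbors_of(c2, nb);
        for (int j : nb)
          if (mask[j] && !basin[j] && values[j] == v) {
            basin[j] = bid;
            stack.push_back(j);
          }
      }
    }
    gstart = gend;
  }

  IntegerVector labels(n, 0);
  for (R_xlen_t i = 0; i < n; ++i) labels[i] = basin[i];
  int nb_basins = (int)basin_min.size();
  NumericVector bmin(nb_basins);
  IntegerVector bvox(nb_basins);
  for (int i = 0; i < nb_basins; ++i) {
    bmin[i] = basin_min[i];
    bvox[i] = basin_argmin[i] + 1; // 1-based linear index for R
  }
  int ne = (int)ev_saddle.size();
  NumericVector es(ne);
  IntegerVector ea(ne), eb(ne);
  for (int i = 0; i < ne; ++i) {
    es[i] = ev_saddle[i];
    ea[i] = ev_a[i];
    eb[i] = ev_b[i];
  }
  return List::create(_["labels"] = labels, _["basin_min"] = bmin,
                      _["basin_voxel"] = bvox, _["saddle"] = es,
                      _["a"] = ea, _["b"] = eb);
}
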