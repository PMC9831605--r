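#include <Rcpp.h>
#include <queue>
#include <set>
#include <map>
#include <cmath>
#include <limits>
#include <algorithm>
using namespace Rcpp;

// voxel linear index convention matches R column-major arrays:
// idx = i + nx*(j + ny*k), all 0-based.

static inline long long vidx(int i, int j, int k, int nx, int ny) {
  return (long long)i + (long long)nx * ((long long)j + (long long)ny * k);
}

// neighbor offsets for 6/18/26 connectivity
static void neighbor_offsets(int connectivity, std::vector<std::array<int,3> > &off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int n = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (n == 0) continue;
        if (connectivity == 6 && n > 1) continue;
        if (connectivity == 18 && n > 2) continue;
        off.push_back({{dx, dy, dz}});
      }
}

// Successive over-relaxation Gauss-Seidel solve of the discrete Laplace
// equation.  code: 0 outside (Neumann: neighbor omitted), 1 domain (unknown),
// 2 source (Dirichlet 0), 3 sink (Dirichlet 1).  Dirichlet values are taken
// to sit on the face between the boundary voxel and the domain (half-voxel
// distance), which the weighted mean encodes as weight 2 for boundary
// neighbors; a 1D slab then converges to the (i + 0.5) / n profile.
// [[Rcpp::export]]
List cpp_solve_laplace(NumericVector init, IntegerVector code, IntegerVector dims,
                       double omega, double tol, int max_iter, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector f = clone(init);
  std::vector<std::array<int,3> > off;
  neighbor_offsets(connectivity, off);
  // collect domain voxels once (usually a small fraction of the grid)
  std::vector<long long> dom;
  for (long long v = 0; v < (long long)code.size(); ++v) {
    if (code[v] == 2) f[v] = 0.0;
    else if (code[v] == 3) f[v] = 1.0;
    if (code[v] == 1) dom.push_back(v);
  }
  double maxupd = R_PosInf;
  int it = 0;
  long long nxy = (long long)nx * ny;
  for (it = 0; it < max_iter && maxupd > tol; ++it) {
    maxupd = 0.0;
    for (size_t d = 0; d < dom.size(); ++d) {
      long long v = dom[d];
      int k = (int)(v / nxy);
      long long r = v - (long long)k * nxy;
      int j = (int)(r / nx);
      int i = (int)(r - (long long)j * nx);
      double s = 0.0; double n = 0.0;
      for (size_t o = 0; o < off.size(); ++o) {
        int ii = i + off[o][0], jj = j + off[o][1], kk = k + off[o][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        long long w = vidx(ii, jj, kk, nx, ny);
        if (code[w] == 0) continue;  // no-flux: omit
        double wt = (code[w] == 2 || code[w] == 3) ? 2.0 : 1.0;
        s += wt * f[w]; n += wt;
      }
      if (n == 0) continue;
      double mean = s / n;
      double nv = (1.0 - omega) * f[v] + omega * mean;
      if (nv < 0.0) nv = 0.0;
      if (nv > 1.0) nv = 1.0;
      double u = std::fabs(nv - f[v]);
      if (u > maxupd) maxupd = u;
      f[v] = nv;
    }
  }
  return List::create(_["field"] = f, _["iterations"] = it, _["max_update"] = maxupd);
}

// Multi-source BFS distance (6-connected graph steps) within a mask.
// Unreachable voxels get Inf.
// [[Rcpp::export]]
NumericVector cpp_bfs_distance(LogicalVector domain, LogicalVector seeds, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long long n = (long long)nx * ny * nz;
  NumericVector dist(n, R_PosInf);
  std::queue<long long> q;
  for (long long v = 0; v < n; ++v)
    if (seeds[v]) { dist[v] = 0.0; q.push(v); }
  std::vector<std::array<int,3> > off;
  neighbor_offsets(6, off);
  long long nxy = (long long)nx * ny;
  while (!q.empty()) {
    long long v = q.front(); q.pop();
    int k = (int)(v / nxy);
    long long r = v - (long long)k * nxy;
    int j = (int)(r / nx);
    int i = (int)(r - (long long)j * nx);
    for (size_t o = 0; o < off.size(); ++o) {
      int ii = i + off[o][0], jj = j + off[o][1], kk = k + off[o][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      long long w = vidx(ii, jj, kk, nx, ny);
      if (!domain[w] || R_finite(dist[w])) continue;
      dist[w] = dist[v] + 1.0;
      q.push(w);
    }
  }
  return dist;
}

// Connected components of a binary mask (1..k labels, 0 outside mask).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long long n = (long long)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3> > off;
  neighbor_offsets(connectivity, off);
  long long nxy = (long long)nx * ny;
  int cur = 0;
  for (long long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    std::queue<long long> q;
    lab[s] = cur; q.push(s);
    while (!q.empty()) {
      long long v = q.front(); q.pop();
      int k = (int)(v / nxy);
      long long r = v - (long long)k * nxy;
      int j = (int)(r / nx);
      int i = (int)(r - (long long)j * nx);
      for (size_t o = 0; o < off.size(); ++o) {
        int ii = i + off[o][0], jj = j + off[o][1], kk = k + off[o][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        long long w = vidx(ii, jj, kk, nx, ny);
        if (mask[w] && lab[w] == 0) { lab[w] = cur; q.push(w); }
      }
    }
  }
  return lab;
}

// Fill unknown voxels with the value of the BFS-nearest known voxel
// (front propagation; ties resolved by scan order, deterministic).
// values: nvox x ncomp.
// [[Rcpp::export]]
NumericMatrix cpp_nearest_fill(NumericMatrix values, LogicalVector known, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long long n = (long long)nx * ny * nz;
  int nc = values.ncol();
  NumericMatrix out = clone(values);
  std::vector<long long> srcof(n, -1);
  std::queue<long long> q;
  for (long long v = 0; v < n; ++v)
    if (known[v]) { srcof[v] = v; q.push(v); }
  std::vector<std::array<int,3> > off;
  neighbor_offsets(6, off);
  long long nxy = (long long)nx * ny;
  while (!q.empty()) {
    long long v = q.front(); q.pop();
    int k = (int)(v / nxy);
    long long r = v - (long long)k * nxy;
    int j = (int)(r / nx);
    int i = (int)(r - (long long)j * nx);
    for (size_t o = 0; o < off.size(); ++o) {
      int ii = i + off[o][0], jj = j + off[o][1], kk = k + off[o][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      long long w = vidx(ii, jj, kk, nx, ny);
      if (srcof[w] >= 0) continue;
      srcof[w] = srcof[v];
      for (int c = 0; c < nc; ++c) out(w, c) = out(srcof[v], c);
      q.push(w);
    }
  }
  return out;
}

// Separable Gaussian smoothing, kernel truncated at 3 sigma and renormalized
// at the borders.  sigma in voxels per axis; sigma <= 0 skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vol, IntegerVector dims, NumericVector sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long long n = (long long)nx * ny * nz;
  NumericVector a = clone(vol), b(n);
  int strides[3] = {1, nx, nx * ny};
  int sizes[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int radius = (int)std::ceil(3.0 * s);
    std::vector<double> kern(2 * radius + 1);
    for (int t = -radius; t <= radius; ++t)
      kern[t + radius] = std::exp(-0.5 * (double)t * t / (s * s));
    int len = sizes[ax];
    long long str = strides[ax];
    // iterate over all lines along axis ax
    long long nlines = n / len;
    int oax1 = (ax + 1) % 3, oax2 = (ax + 2) % 3;
    for (long long ln = 0; ln < nlines; ++ln) {
      long long p1 = ln % sizes[oax1], p2 = ln / sizes[oax1];
      long long base = p1 * strides[oax1] + p2 * strides[oax2];
      for (int t = 0; t < len; ++t) {
        double acc = 0.0, wsum = 0.0;
        int lo = std::max(0, t - radius), hi = std::min(len - 1, t + radius);
        for (int u = lo; u <= hi; ++u) {
          double w = kern[u - t + radius];
          acc += w * a[base + (long long)u * str];
          wsum += w;
        }
        b[base + (long long)t * str] = acc / wsum;
      }
    }
    std::swap(a, b);
  }
  return a;
}

// Trilinear sampling of a 3D volume at continuous 0-based voxel coordinates.
// Points outside [0, dim-1] in any axis yield NA.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims, NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int m = pts.nrow();
  NumericVector out(m);
  for (int p = 0; p < m; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z) ||
        x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[p] = NA_REAL; continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) --i0;
    if (j0 == ny - 1) --j0;
    if (k0 == nz - 1) --k0;
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double acc = 0.0;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          int ii = std::min(i0 + di, nx - 1), jj = std::min(j0 + dj, ny - 1), kk = std::min(k0 + dk, nz - 1);
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          acc += w * vol[vidx(ii, jj, kk, nx, ny)];
        }
    out[p] = acc;
  }
  return out;
}

// Nearest-neighbour sampling at continuous 0-based voxel coordinates.
// [[Rcpp::export]]
NumericVector cpp_nearest_sample(NumericVector vol, IntegerVector dims, NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int m = pts.nrow();
  NumericVector out(m);
  for (int p = 0; p < m; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z)) { out[p] = NA_REAL; continue; }
    int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) { out[p] = NA_REAL; continue; }
    out[p] = vol[vidx(i, j, k, nx, ny)];
  }
  return out;
}

// ---- scattered interpolation: grid-hashed kNN + weighted local affine fit ----

struct HashGrid {
  double ox, oy, oz, cell;
  int gx, gy, gz;
  std::vector<std::vector<int> > bins;
};

static void build_grid(const NumericMatrix &sites, double cell, HashGrid &g) {
  int n = sites.nrow();
  double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
  double xmax = R_NegInf, ymax = R_NegInf, zmax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, sites(i, 0)); xmax = std::max(xmax, sites(i, 0));
    ymin = std::min(ymin, sites(i, 1)); ymax = std::max(ymax, sites(i, 1));
    zmin = std::min(zmin, sites(i, 2)); zmax = std::max(zmax, sites(i, 2));
  }
  g.cell = cell; g.ox = xmin; g.oy = ymin; g.oz = zmin;
  g.gx = std::max(1, (int)std::floor((xmax - xmin) / cell) + 1);
  g.gy = std::max(1, (int)std::floor((ymax - ymin) / cell) + 1);
  g.gz = std::max(1, (int)std::floor((zmax - zmin) / cell) + 1);
  g.bins.assign((size_t)g.gx * g.gy * g.gz, std::vector<int>());
  for (int i = 0; i < n; ++i) {
    int cx = std::min(g.gx - 1, std::max(0, (int)std::floor((sites(i, 0) - g.ox) / cell)));
    int cy = std::min(g.gy - 1, std::max(0, (int)std::floor((sites(i, 1) - g.oy) / cell)));
    int cz = std::min(g.gz - 1, std::max(0, (int)std::floor((sites(i, 2) - g.oz) / cell)));
    g.bins[(size_t)cx + (size_t)g.gx * (cy + (size_t)g.gy * cz)].push_back(i);
  }
}

// Solve symmetric 4x4 system by Gaussian elimination with partial pivoting.
// Returns false if near-singular.
static bool solve4(double A[4][4], double b[4][3], int nc, double out[4][3]) {
  int piv[4] = {0, 1, 2, 3};
  double M[4][5 + 2];
  (void)M;
  double a[4][4];
  double rhs[4][3];
  for (int i = 0; i < 4; ++i) { for (int j = 0; j < 4; ++j) a[i][j] = A[i][j]; for (int c = 0; c < nc; ++c) rhs[i][c] = b[i][c]; }
  for (int col = 0; col < 4; ++col) {
    int best = col; double bv = std::fabs(a[col][col]);
    for (int r = col + 1; r < 4; ++r) if (std::fabs(a[r][col]) > bv) { bv = std::fabs(a[r][col]); best = r; }
    if (bv < 1e-12) return false;
    if (best != col) {
      for (int j = 0; j < 4; ++j) std::swap(a[col][j], a[best][j]);
      for (int c = 0; c < nc; ++c) std::swap(rhs[col][c], rhs[best][c]);
      std::swap(piv[col], piv[best]);
    }
    for (int r = col + 1; r < 4; ++r) {
      double f = a[r][col] / a[col][col];
      for (int j = col; j < 4; ++j) a[r][j] -= f * a[col][j];
      for (int c = 0; c < nc; ++c) rhs[r][c] -= f * rhs[col][c];
    }
  }
  for (int col = 3; col >= 0; --col) {
    for (int c = 0; c < nc; ++c) {
      double s = rhs[col][c];
      for (int j = col + 1; j < 4; ++j) s -= a[col][j] * out[j][c];
      out[col][c] = s / a[col][col];
    }
  }
  return true;
}

// Moving-least-squares scattered interpolation: for each query, take the k
// nearest sites (grid-hashed search) and fit a weighted affine model
// y ~ b0 + B (x - q); the intercept b0 is the interpolated value.  Exactly
// reproduces globally affine site->value maps.  Falls back to the weighted
// mean of the neighbourhood when the local fit is degenerate.
// [[Rcpp::export]]
NumericMatrix cpp_mls_interp(NumericMatrix sites, NumericMatrix values,
                             NumericMatrix queries, int k, double cell) {
  int n = sites.nrow(), m = queries.nrow(), nc = values.ncol();
  if (nc > 3) stop("at most 3 value components supported");
  NumericMatrix out(m, nc);
  HashGrid g;
  build_grid(sites, cell, g);
  std::vector<std::pair<double, int> > cand;
  for (int q = 0; q < m; ++q) {
    double qx = queries(q, 0), qy = queries(q, 1), qz = queries(q, 2);
    int cx = (int)std::floor((qx - g.ox) / g.cell);
    int cy = (int)std::floor((qy - g.oy) / g.cell);
    int cz = (int)std::floor((qz - g.oz) / g.cell);
    cand.clear();
    int ring = 0;
    // expand rings until we have >= k candidates whose distance bound is safe
    while ((int)cand.size() < k || true) {
      bool any_cells = false;
      if (ring == 0) {
        int bx = std::min(g.gx - 1, std::max(0, cx));
        int by = std::min(g.gy - 1, std::max(0, cy));
        int bz = std::min(g.gz - 1, std::max(0, cz));
        // handled in loop below
      }
      for (int dz = -ring; dz <= ring; ++dz)
        for (int dy = -ring; dy <= ring; ++dy)
          for (int dx = -ring; dx <= ring; ++dx) {
            if (std::max(std::max(std::abs(dx), std::abs(dy)), std::abs(dz)) != ring) continue;
            int bx = cx + dx, by = cy + dy, bz = cz + dz;
            if (bx < 0 || by < 0 || bz < 0 || bx >= g.gx || by >= g.gy || bz >= g.gz) continue;
            any_cells = true;
            const std::vector<int> &bin = g.bins[(size_t)bx + (size_t)g.gx * (by + (size_t)g.gy * bz)];
            for (size_t t = 0; t < bin.size(); ++t) {
              int s = bin[t];
              double dxx = sites(s, 0) - qx, dyy = sites(s, 1) - qy, dzz = sites(s, 2) - qz;
              cand.push_back(std::make_pair(dxx * dxx + dyy * dyy + dzz * dzz, s));
            }
          }
      // stop when enough candidates and the next ring cannot contain closer
      // points than the k-th found so far
      if ((int)cand.size() >= k) {
        std::nth_element(cand.begin(), cand.begin() + (k - 1), cand.end());
        double dk = std::sqrt(cand[k - 1].first);
        if (dk <= ring * g.cell) break;
      }
      // safety: if the ring has grown past the whole grid, stop
      if (!any_cells && ring > g.gx + g.gy + g.gz) break;
      ++ring;
    }
    int kmax = std::min((int)cand.size(), 4 * k);
    if (kmax == 0) { for (int c = 0; c < nc; ++c) out(q, c) = NA_REAL; continue; }
    std::partial_sort(cand.begin(), cand.begin() + kmax, cand.end());
    // weighted affine LS on centred coordinates; if the k nearest sites are
    // (nearly) coplanar the neighbourhood is grown before giving up
    bool ok = false;
    double coef[4][3];
    double wsum = 0.0, wmean[3] = {0, 0, 0};
    for (int kk = std::min(kmax, k); !ok && kk <= kmax; kk *= 2) {
      if (kk > kmax) break;
      double A[4][4] = {{0}};
      double bb[4][3] = {{0}};
      wsum = 0.0; wmean[0] = wmean[1] = wmean[2] = 0.0;
      double scale = std::sqrt(cand[kk - 1].first) + 1e-12;
      for (int t = 0; t < kk; ++t) {
        int s = cand[t].second;
        double d = std::sqrt(cand[t].first);
        double w = 1.0 / (d / scale + 1e-3);
        double X[4] = {1.0, sites(s, 0) - qx, sites(s, 1) - qy, sites(s, 2) - qz};
        for (int i = 0; i < 4; ++i)
          for (int j = 0; j < 4; ++j) A[i][j] += w * X[i] * X[j];
        for (int c = 0; c < nc; ++c)
          for (int i = 0; i < 4; ++i) bb[i][c] += w * X[i] * values(s, c);
        wsum += w;
        for (int c = 0; c < nc; ++c) wmean[c] += w * values(s, c);
      }
      ok = (kk >= 4) && solve4(A, bb, nc, coef);
      if (kk == kmax) break;
      if (kk * 2 > kmax && !ok) kk = kmax / 2;  // last try uses all candidates
    }
    for (int c = 0; c < nc; ++c)
      out(q, c) = ok ? coef[0][c] : wmean[c] / wsum;
  }
  return out;
}

// ---- mesh decimation by shortest-edge collapse ----

// Collapse the shortest native-space edge (removing an interior endpoint,
// or sliding along the boundary when both endpoints are boundary and the
// edge itself is a boundary edge) until the median native edge length
// reaches target.  Link condition enforced to keep the sheet manifold; when
// 2D parameter coordinates (uv) are supplied, collapses that would create a
// degenerate or flipped triangle in the parameter plane are rejected, which
// keeps winding consistent and parameter-space areas positive.
// tris are 0-based on input.  Returns kept-vertex mask and new triangles.
// [[Rcpp::export]]
List cpp_decimate_edges(NumericMatrix verts, NumericMatrix uv,
                        IntegerMatrix tris0, double target) {
  int nv = verts.nrow(), nt = tris0.nrow();
  std::vector<std::array<int,3> > tris(nt);
  for (int t = 0; t < nt; ++t) tris[t] = {{tris0(t,0), tris0(t,1), tris0(t,2)}};
  std::vector<char> valive(nv, 1), talive(nt, 1);
  // vertex -> incident triangles
  std::vector<std::vector<int> > vtri(nv);
  for (int t = 0; t < nt; ++t)
    for (int c = 0; c < 3; ++c) vtri[tris[t][c]].push_back(t);

  bool have_uv = uv.nrow() == nv;
  // reference orientation in the parameter plane (sign of the first triangle)
  double orient = 1.0;
  if (have_uv && nt > 0) {
    int a0 = tris[0][0], b0 = tris[0][1], c0 = tris[0][2];
    double s = (uv(b0,0)-uv(a0,0)) * (uv(c0,1)-uv(a0,1)) -
               (uv(b0,1)-uv(a0,1)) * (uv(c0,0)-uv(a0,0));
    orient = (s >= 0) ? 1.0 : -1.0;
  }
  auto uv_area_ok = [&](int va, int vb, int vc) {
    if (!have_uv) return true;
    double s = (uv(vb,0)-uv(va,0)) * (uv(vc,1)-uv(va,1)) -
               (uv(vb,1)-uv(va,1)) * (uv(vc,0)-uv(va,0));
    return orient * s > 1e-12;
  };
  auto edge_key = [](int a, int b) { return ((long long)std::min(a,b) << 32) | (unsigned int)std::max(a,b); };
  auto elen = [&](int a, int b) {
    double dx = verts(a,0)-verts(b,0), dy = verts(a,1)-verts(b,1), dz = verts(a,2)-verts(b,2);
    return std::sqrt(dx*dx + dy*dy + dz*dz);
  };
  auto edge_tri_count = [&](int a, int b) {
    int cnt = 0;
    for (size_t x = 0; x < vtri[a].size(); ++x) {
      int t = vtri[a][x];
      if (!talive[t]) continue;
      bool hasb = (tris[t][0]==b || tris[t][1]==b || tris[t][2]==b);
      if (hasb) ++cnt;
    }
    return cnt;
  };
  auto is_boundary_vertex = [&](int a) {
    // a vertex is boundary if any incident edge has exactly one live triangle
    std::map<int,int> cnt;
    for (size_t x = 0; x < vtri[a].size(); ++x) {
      int t = vtri[a][x];
      if (!talive[t]) continue;
      for (int c = 0; c < 3; ++c) {
        int u = tris[t][c];
        if (u != a) cnt[u]++;
      }
    }
    for (std::map<int,int>::iterator it = cnt.begin(); it != cnt.end(); ++it)
      if (it->second == 1) return true;
    return false;
  };

  // priority queue of edges by length, lazy invalidation
  typedef std::tuple<double,int,int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  std::set<long long> seen;
  for (int t = 0; t < nt; ++t)
    for (int c = 0; c < 3; ++c) {
      int a = tris[t][c], b = tris[t][(c+1)%3];
      long long k = edge_key(a, b);
      if (seen.insert(k).second) pq.push(QE(elen(a,b), std::min(a,b), std::max(a,b)));
    }

  auto median_edge = [&]() {
    std::vector<double> ls;
    std::set<long long> done;
    for (int t = 0; t < nt; ++t) {
      if (!talive[t]) continue;
      for (int c = 0; c < 3; ++c) {
        int a = tris[t][c], b = tris[t][(c+1)%3];
        if (done.insert(edge_key(a,b)).second) ls.push_back(elen(a,b));
      }
    }
    if (ls.empty()) return R_PosInf;
    size_t mid = ls.size() / 2;
    std::nth_element(ls.begin(), ls.begin() + mid, ls.end());
    double m = ls[mid];
    if (ls.size() % 2 == 0) {
      double lo = *std::max_element(ls.begin(), ls.begin() + mid);
      m = 0.5 * (m + lo);
    }
    return m;
  };

  int since_check = 0;
  int n_alive = nv;
  // stop-criterion granularity: re-check the median after ~2% of the live
  // vertices have been collapsed (at least every collapse on small meshes)
  int interval = std::max(1, n_alive / 50);
  double med = median_edge();
  if (med >= target)
    ; // nothing to do
  else while (!pq.empty()) {
    QE e = pq.top(); pq.pop();
    int a = std::get<1>(e), b = std::get<2>(e);
    if (!valive[a] || !valive[b]) continue;
    double l = elen(a, b);
    if (std::fabs(l - std::get<0>(e)) > 1e-12) { pq.push(QE(l, a, b)); continue; }
    int ntri = edge_tri_count(a, b);
    if (ntri == 0) continue;  // stale edge
    bool ba = is_boundary_vertex(a), bbnd = is_boundary_vertex(b);
    int rem, keep;
    if (!ba) { rem = a; keep = b; }
    else if (!bbnd) { rem = b; keep = a; }
    else if (ntri == 1) { rem = a; keep = b; }  // boundary edge: slide along boundary
    else continue;  // interior edge between two boundary vertices: skip
    // link condition: common live neighbours of rem and keep must be exactly
    // the opposite vertices of the triangles sharing edge (rem,keep)
    std::set<int> nrem, nkeep, opp;
    for (size_t x = 0; x < vtri[rem].size(); ++x) {
      int t = vtri[rem][x]; if (!talive[t]) continue;
      bool haskeep = false; int other = -1;
      for (int c = 0; c < 3; ++c) {
        int u = tris[t][c];
        if (u == keep) haskeep = true;
        if (u != rem) nrem.insert(u);
        if (u != rem && u != keep) other = u;
      }
      if (haskeep && other >= 0) opp.insert(other);
    }
    for (size_t x = 0; x < vtri[keep].size(); ++x) {
      int t = vtri[keep][x]; if (!talive[t]) continue;
      for (int c = 0; c < 3; ++c) if (tris[t][c] != keep) nkeep.insert(tris[t][c]);
    }
    std::vector<int> common;
    for (std::set<int>::iterator it = nrem.begin(); it != nrem.end(); ++it)
      if (*it != keep && nkeep.count(*it)) common.push_back(*it);
    bool linkok = common.size() == opp.size();
    if (linkok)
      for (size_t x = 0; x < common.size(); ++x)
        if (!opp.count(common[x])) { linkok = false; break; }
    if (!linkok) continue;
    // parameter-plane validity: re-pointed triangles must keep positive area
    bool uv_ok = true;
    for (size_t x = 0; x < vtri[rem].size() && uv_ok; ++x) {
      int t = vtri[rem][x];
      if (!talive[t]) continue;
      bool haskeep = (tris[t][0]==keep || tris[t][1]==keep || tris[t][2]==keep);
      if (haskeep) continue;  // triangle disappears
      int nvx[3];
      for (int c = 0; c < 3; ++c) nvx[c] = (tris[t][c] == rem) ? keep : tris[t][c];
      if (!uv_area_ok(nvx[0], nvx[1], nvx[2])) uv_ok = false;
    }
    if (!uv_ok) continue;
    // uniformity bound: a collapse must not create edges far above the
    // target spacing, which would let one vertex cascade-absorb the mesh
    bool too_long = false;
    for (std::set<int>::iterator it = nrem.begin(); it != nrem.end() && !too_long; ++it)
      if (*it != keep && valive[*it] && elen(keep, *it) > 2.2 * target)
        too_long = true;
    if (too_long) continue;
    // collapse rem -> keep
    valive[rem] = 0;
    for (size_t x = 0; x < vtri[rem].size(); ++x) {
      int t = vtri[rem][x];
      if (!talive[t]) continue;
      bool haskeep = (tris[t][0]==keep || tris[t][1]==keep || tris[t][2]==keep);
      if (haskeep) { talive[t] = 0; continue; }
      for (int c = 0; c < 3; ++c) if (tris[t][c] == rem) tris[t][c] = keep;
      vtri[keep].push_back(t);
    }
    // push new edges around keep
    for (size_t x = 0; x < vtri[keep].size(); ++x) {
      int t = vtri[keep][x]; if (!talive[t]) continue;
      for (int c = 0; c < 3; ++c) {
        int u = tris[t][c];
        if (u != keep && valive[u]) pq.push(QE(elen(keep, u), std::min(keep,u), std::max(keep,u)));
      }
    }
    --n_alive;
    if (++since_check >= interval) {
      since_check = 0;
      interval = std::max(1, n_alive / 50);
      if (median_edge() >= target) break;
    }
  }
  LogicalVector kept(nv);
  for (int v = 0; v < nv; ++v) kept[v] = valive[v] != 0;
  std::vector<int> keep_tris;
  for (int t = 0; t < nt; ++t) if (talive[t]) keep_tris.push_back(t);
  IntegerMatrix newt(keep_tris.size(), 3);
  for (size_t t = 0; t < keep_tris.size(); ++t)
    for (int c = 0; c < 3; ++c) newt(t, c) = tris[keep_tris[t]][c];
  return List::create(_["kept"] = kept, _["triangles"] = newt);
}
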