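#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---- Felzenszwalb-Huttenlocher 1D squared distance transform ----
// f: input squared distances (INF where no site), step: sample spacing (mm).
static void dt1d(std::vector<double> &f, double step) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
          (2.0 * s2 * q - 2.0 * s2 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]) * step;
    d[q] = dq * dq + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Squared Euclidean distance (mm^2) from each voxel to the nearest TRUE voxel.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e30;
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = mask[i] ? 0.0 : INF;
  std::vector<double> buf;
  // x pass
  buf.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) buf[x] = out[base + x];
      dt1d(buf, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = buf[x];
    }
  // y pass
  buf.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) buf[y] = out[base + (R_xlen_t)y * nx];
      dt1d(buf, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = buf[y];
    }
  // z pass
  buf.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) buf[z] = out[base + (R_xlen_t)z * nx * ny];
      dt1d(buf, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nx * ny] = buf[z];
    }
  return out;
}

// 6-connected component labelling; returns integer labels (0 = background),
// with label 1 assigned to the largest component.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(N, 0);
  std::vector<R_xlen_t> sizes; // per label
  int next = 0;
  std::queue<R_xlen_t> q;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t i0 = 0; i0 < N; ++i0) {
    if (!mask[i0] || lab[i0] != 0) continue;
    ++next;
    sizes.push_back(0);
    lab[i0] = next;
    q.push(i0);
    while (!q.empty()) {
      R_xlen_t i = q.front(); q.pop();
      ++sizes[next - 1];
      int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / sz);
      R_xlen_t nb[6]; int nn = 0;
      if (x > 0) nb[nn++] = i - sx;
      if (x < nx - 1) nb[nn++] = i + sx;
      if (y > 0) nb[nn++] = i - sy;
      if (y < ny - 1) nb[nn++] = i + sy;
      if (z > 0) nb[nn++] = i - sz;
      if (z < nz - 1) nb[nn++] = i + sz;
      for (int k = 0; k < nn; ++k) {
        R_xlen_t j = nb[k];
        if (mask[j] && lab[j] == 0) { lab[j] = next; q.push(j); }
      }
    }
  }
  if (next > 1) {
    int big = 1;
    for (int l = 2; l <= next; ++l) if (sizes[l - 1] > sizes[big - 1]) big = l;
    if (big != 1)
      for (R_xlen_t i = 0; i < N; ++i) {
        if (lab[i] == big) lab[i] = 1;
        else if (lab[i] == 1) lab[i] = big;
      }
  }
  return lab;
}

// ---- gamma index search ----
struct Off { double dx, dy, dz, d2; };

static void build_shell(std::vector<Off> &shell, int k, double dta, double step) {
  // lattice offsets with distance in [k*dta, (k+1)*dta)
  shell.clear();
  const double lo2 = (k * dta) * (k * dta);
  const double hi = (k + 1) * dta;
  const double hi2 = hi * hi;
  const int m = (int)std::ceil(hi / step);
  for (int a = -m; a <= m; ++a)
    for (int b = -m; b <= m; ++b)
      for (int c = -m; c <= m; ++c) {
        double dx = a * step, dy = b * step, dz = c * step;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 >= hi2) continue;
        if (k > 0 && d2 < lo2) continue;
        shell.push_back({dx, dy, dz, d2});
      }
  std::sort(shell.begin(), shell.end(),
            [](const Off &u, const Off &v) { return u.d2 < v.d2; });
}

// Per-voxel gamma for reference voxels `idx` (1-based linear indices).
// Positions are voxel-centre world coordinates implied by spacing (origin
// cancels since both grids are congruent). The evaluated dose is trilinearly
// interpolated at candidate offsets on a lattice of step `step` (<= dta/10 by
// default), searched in shells of width dta outward until the distance term
// alone exceeds the running minimum, capped at `cap`.
// [[Rcpp::export]]
NumericVector gamma_search_cpp(NumericVector ref, NumericVector ev,
                               IntegerVector dims, NumericVector spacing,
                               IntegerVector idx, double dta, double dd_abs,
                               double step, double cap) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const R_xlen_t strx = 1, stry = nx, strz = (R_xlen_t)nx * ny;
  const int max_shell = (int)std::ceil(cap) + 1;
  std::vector<std::vector<Off>> shells(max_shell);
  std::vector<bool> built(max_shell, false);
  NumericVector out(idx.size());
  const double dta2 = dta * dta, dd2 = dd_abs * dd_abs;

  for (R_xlen_t q = 0; q < idx.size(); ++q) {
    R_xlen_t i = (R_xlen_t)idx[q] - 1;
    int vx = (int)(i % nx), vy = (int)((i / nx) % ny), vz = (int)(i / strz);
    double px = vx * sx, py = vy * sy, pz = vz * sz;
    double dref = ref[i];
    double g2min = cap * cap;
    for (int k = 0; k < max_shell; ++k) {
      if ((double)k * k >= g2min) break;
      if (!built[k]) { build_shell(shells[k], k, dta, step); built[k] = true; }
      const std::vector<Off> &sh = shells[k];
      for (size_t s = 0; s < sh.size(); ++s) {
        double dterm = sh[s].d2 / dta2;
        if (dterm >= g2min) break;
        double x = (px + sh[s].dx) / sx, y = (py + sh[s].dy) / sy,
               z = (pz + sh[s].dz) / sz;
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
        if (x0 < 0 || y0 < 0 || z0 < 0 || x0 >= nx - 1 || y0 >= ny - 1 ||
            z0 >= nz - 1) {
          // allow exactly-on-far-face samples
          if (x == (double)(nx - 1)) x0 = nx - 2;
          if (y == (double)(ny - 1)) y0 = ny - 2;
          if (z == (double)(nz - 1)) z0 = nz - 2;
          if (x0 < 0 || y0 < 0 || z0 < 0 || x0 >= nx - 1 || y0 >= ny - 1 ||
              z0 >= nz - 1)
            continue;
        }
        double tx = x - x0, ty = y - y0, tz = z - z0;
        R_xlen_t b = x0 * strx + (R_xlen_t)y0 * stry + (R_xlen_t)z0 * strz;
        double v00 = ev[b] * (1 - tx) + ev[b + 1] * tx;
        double v10 = ev[b + stry] * (1 - tx) + ev[b + stry + 1] * tx;
        double v01 = ev[b + strz] * (1 - tx) + ev[b + strz + 1] * tx;
        double v11 = ev[b + stry + strz] * (1 - tx) + ev[b + stry + strz + 1] * tx;
        double de = (v00 * (1 - ty) + v10 * ty) * (1 - tz) +
                    (v01 * (1 - ty) + v11 * ty) * tz;
        double diff = de - dref;
        double g2 = dterm + diff * diff / dd2;
        if (g2 < g2min) g2min = g2;
      }
    }
    out[q] = std::sqrt(g2min);
  }
  return out;
}
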