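// Low-level 3D grid kernels shared by the pipeline modules.
//
// All arrays use R's column-major layout with dim = c(nz, ny, nx):
// linear index = z + nz * (y + ny * x), 0-based here.
// Spacing / origin vectors are ordered (z, y, x) in micrometres.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

typedef R_xlen_t xlen;

static inline xlen lidx(int z, int y, int x, int nz, int ny) {
  return (xlen)z + (xlen)nz * ((xlen)y + (xlen)ny * (xlen)x);
}

// reflect index into [0, n)
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// ---------------------------------------------------------------- median ----

// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector vol, IntegerVector dim, int radius) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out(vol.size());
  const int w = 2 * radius + 1;
  std::vector<double> buf((size_t)w * w * w);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        size_t k = 0;
        for (int dx = -radius; dx <= radius; ++dx) {
          const int xx = reflect(x + dx, nx);
          for (int dy = -radius; dy <= radius; ++dy) {
            const int yy = reflect(y + dy, ny);
            for (int dz = -radius; dz <= radius; ++dz) {
              const int zz = reflect(z + dz, nz);
              buf[k++] = vol[lidx(zz, yy, xx, nz, ny)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
        out[lidx(z, y, x, nz, ny)] = buf[k / 2];
      }
    }
  }
  return out;
}

// ------------------------------------------------------------------- EDT ----

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with grid step s.
static void dt1d(std::vector<double>& f, std::vector<double>& d, int n, double s,
                 std::vector<int>& v, std::vector<double>& zb) {
  int k = -1;
  const double s2 = s * s;
  // build the lower envelope over the finite parabolas only
  for (int q = 0; q < n; ++q) {
    if (f[q] == HUGE_VAL) continue;
    double sIntersect = 0.0;
    while (k >= 0) {
      const int p = v[k];
      sIntersect = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (sIntersect > zb[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    zb[k] = (k == 0) ? -HUGE_VAL : sIntersect;
    zb[k + 1] = HUGE_VAL;
  }
  if (k < 0) {  // no finite source in this line
    for (int q = 0; q < n; ++q) d[q] = HUGE_VAL;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    const double dq = s * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (um) from every voxel to the nearest TRUE voxel.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector sites, IntegerVector dim, NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  NumericVector out(sites.size());
  for (xlen i = 0; i < sites.size(); ++i)
    out[i] = sites[i] ? 0.0 : HUGE_VAL;
  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> zb(nmax + 1);

  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      bool any = false;
      for (int z = 0; z < nz; ++z) { f[z] = out[lidx(z, y, x, nz, ny)]; if (f[z] < HUGE_VAL) any = true; }
      if (!any) continue;
      dt1d(f, d, nz, sz, v, zb);
      for (int z = 0; z < nz; ++z) out[lidx(z, y, x, nz, ny)] = d[z];
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      bool any = false;
      for (int y = 0; y < ny; ++y) { f[y] = out[lidx(z, y, x, nz, ny)]; if (f[y] < HUGE_VAL) any = true; }
      if (!any) continue;
      dt1d(f, d, ny, sy, v, zb);
      for (int y = 0; y < ny; ++y) out[lidx(z, y, x, nz, ny)] = d[y];
    }
  // pass along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      bool any = false;
      for (int x = 0; x < nx; ++x) { f[x] = out[lidx(z, y, x, nz, ny)]; if (f[x] < HUGE_VAL) any = true; }
      if (!any) continue;
      dt1d(f, d, nx, sx, v, zb);
      for (int x = 0; x < nx; ++x) out[lidx(z, y, x, nz, ny)] = d[x];
    }
  for (xlen i = 0; i < out.size(); ++i)
    out[i] = (out[i] == HUGE_VAL) ? R_PosInf : std::sqrt(out[i]);
  return out;
}

// -------------------------------------------------- connected components ----

// Label connected components of a binary mask; connectivity 6 or 26.
// Labels assigned in scan order, 1-based; background = 0.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<int> dzv, dyv, dxv;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        const int man = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && man != 1) continue;
        dzv.push_back(dz); dyv.push_back(dy); dxv.push_back(dx);
      }
  int next = 0;
  std::vector<xlen> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const xlen i = lidx(z, y, x, nz, ny);
        if (!mask[i] || lab[i]) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          const xlen j = stack.back();
          stack.pop_back();
          const int jx = (int)(j / ((xlen)nz * ny));
          const int jy = (int)((j / nz) % ny);
          const int jz = (int)(j % nz);
          for (size_t q = 0; q < dzv.size(); ++q) {
            const int zz = jz + dzv[q], yy = jy + dyv[q], xx = jx + dxv[q];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            const xlen jj = lidx(zz, yy, xx, nz, ny);
            if (mask[jj] && !lab[jj]) { lab[jj] = next; stack.push_back(jj); }
          }
        }
      }
  return lab;
}

// Fill background cavities not 6-connected to the volume border.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes3d(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<char> reach(mask.size(), 0);
  std::vector<xlen> stack;
  // seed all border background voxels
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        if (z != 0 && z != nz - 1 && y != 0 && y != ny - 1 && x != 0 && x != nx - 1)
          continue;
        const xlen i = lidx(z, y, x, nz, ny);
        if (!mask[i] && !reach[i]) { reach[i] = 1; stack.push_back(i); }
      }
  const int dz6[6] = {1, -1, 0, 0, 0, 0};
  const int dy6[6] = {0, 0, 1, -1, 0, 0};
  const int dx6[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    const xlen j = stack.back();
    stack.pop_back();
    const int jx = (int)(j / ((xlen)nz * ny));
    const int jy = (int)((j / nz) % ny);
    const int jz = (int)(j % nz);
    for (int q = 0; q < 6; ++q) {
      const int zz = jz + dz6[q], yy = jy + dy6[q], xx = jx + dx6[q];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      const xlen jj = lidx(zz, yy, xx, nz, ny);
      if (!mask[jj] && !reach[jj]) { reach[jj] = 1; stack.push_back(jj); }
    }
  }
  LogicalVector out(mask.size());
  for (xlen i = 0; i < mask.size(); ++i) out[i] = mask[i] || !reach[i];
  return out;
}

// ------------------------------------------------------------- thinning -----

// Simple-point test for (26, 6) connectivity (Malandain & Bertrand):
// a voxel is simple iff
//   (a) the object voxels of its 26-neighbourhood form exactly one
//       26-connected component, and
//   (b) the background voxels of its 18-neighbourhood that are 6-adjacent to
//       the centre form exactly one 6-connected component within N18.
// nb: 27 bools for the 3x3x3 cube in (z,y,x) minor-to-major order, centre = 13.
static inline int cube_i(int dz, int dy, int dx) {
  return (dz + 1) + 3 * ((dy + 1) + 3 * (dx + 1));
}

static bool is_simple(const bool nb[27]) {
  // (a) 26-components of object in N26
  {
    int seen[27]; bool obj[27];
    int cnt = 0;
    for (int i = 0; i < 27; ++i) { seen[i] = 0; obj[i] = (i != 13) && nb[i]; }
    int stack[27], top;
    for (int i = 0; i < 27; ++i) {
      if (!obj[i] || seen[i]) continue;
      ++cnt;
      if (cnt > 1) return false;
      top = 0; stack[top++] = i; seen[i] = 1;
      while (top) {
        const int j = stack[--top];
        const int jz = j % 3, jy = (j / 3) % 3, jx = j / 9;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              const int zz = jz + dz, yy = jy + dy, xx = jx + dx;
              if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2) continue;
              const int jj = zz + 3 * (yy + 3 * xx);
              if (obj[jj] && !seen[jj]) { seen[jj] = 1; stack[top++] = jj; }
            }
      }
    }
    if (cnt != 1) return false;
  }
  // (b) 6-components of background within N18, touching a 6-neighbour of centre
  {
    bool in18[27], bg[27];
    for (int i = 0; i < 27; ++i) {
      const int dz = i % 3 - 1, dy = (i / 3) % 3 - 1, dx = i / 9 - 1;
      const int man = std::abs(dz) + std::abs(dy) + std::abs(dx);
      in18[i] = (man >= 1 && man <= 2);
      bg[i] = in18[i] && !nb[i];
    }
    int seen[27] = {0};
    int cnt = 0;
    int stack[27], top;
    for (int s = 0; s < 27; ++s) {
      const int dz = s % 3 - 1, dy = (s / 3) % 3 - 1, dx = s / 9 - 1;
      if (std::abs(dz) + std::abs(dy) + std::abs(dx) != 1) continue;  // 6-neighbours
      if (!bg[s] || seen[s]) continue;
      ++cnt;
      if (cnt > 1) return false;
      top = 0; stack[top++] = s; seen[s] = 1;
      while (top) {
        const int j = stack[--top];
        const int jz = j % 3, jy = (j / 3) % 3, jx = j / 9;
        const int step[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
        for (int q = 0; q < 6; ++q) {
          const int zz = jz + step[q][0], yy = jy + step[q][1], xx = jx + step[q][2];
          if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2) continue;
          const int jj = zz + 3 * (yy + 3 * xx);
          if (bg[jj] && !seen[jj]) { seen[jj] = 1; stack[top++] = jj; }
        }
      }
    }
    if (cnt != 1) return false;
  }
  return true;
}

// Sequential topology-preserving thinning to a 1-voxel curve skeleton.
// Candidates are removed in increasing distance-to-background order (so the
// skeleton tracks the medial ridge); curve endpoints (<= 1 object neighbour)
// are never removed. Assumes an isotropic grid.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  LogicalVector cur(clone(mask));
  // squared distance to background on the unit grid (isotropic assumption)
  NumericVector spacing = NumericVector::create(1.0, 1.0, 1.0);
  LogicalVector bg(mask.size());
  for (xlen i = 0; i < mask.size(); ++i) bg[i] = !mask[i];
  NumericVector dist = cpp_edt3d(bg, dim, spacing);

  // six directional subpasses per iteration (borders of one face direction
  // at a time): prevents scan-order "zippering" of thin structures while the
  // EDT ordering keeps deletions tracking the medial ridge
  const int step6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  std::vector<std::pair<double, xlen> > cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
    cand.clear();
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          const xlen i = lidx(z, y, x, nz, ny);
          if (!cur[i]) continue;
          // border voxel in direction d: that 6-neighbour is background
          const int zz = z + step6[d][0], yy = y + step6[d][1], xx = x + step6[d][2];
          const bool border =
            (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx ||
             !cur[lidx(zz, yy, xx, nz, ny)]);
          if (border) cand.push_back(std::make_pair(dist[i], i));
        }
    std::sort(cand.begin(), cand.end());
    for (size_t q = 0; q < cand.size(); ++q) {
      const xlen i = cand[q].second;
      if (!cur[i]) continue;
      const int ix = (int)(i / ((xlen)nz * ny));
      const int iy = (int)((i / nz) % ny);
      const int iz = (int)(i % nz);
      bool nb[27];
      int nnb = 0;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            const int zz = iz + dz, yy = iy + dy, xx = ix + dx;
            bool val = false;
            if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
              val = cur[lidx(zz, yy, xx, nz, ny)];
            nb[cube_i(dz, dy, dx)] = val;
            if (val && !(dz == 0 && dy == 0 && dx == 0)) ++nnb;
          }
      // keep curve endpoints (<= 1 neighbour) and 2-neighbour chain/corner
      // voxels: deleting the latter shortens or "zippers" thin structures
      // (deletion order would otherwise consume a 2-voxel-wide ribbon
      // axially); with >= 3 neighbours required, a 2-wide ribbon resolves
      // to a clean 1-wide curve instead
      if (nnb <= 2) continue;
      if (!is_simple(nb)) continue;
      cur[i] = false;
      changed = true;
    }
    }
  }
  return cur;
}

// ------------------------------------------------------------- raycasting ---

// trilinear sample of a 0/1 mask at a world point (um); outside => 0
static double sample_tri(const LogicalVector& mask, int nz, int ny, int nx,
                         double sz, double sy, double sx,
                         double oz, double oy, double ox,
                         double pz, double py, double px) {
  const double cz = (pz - oz) / sz - 0.5;
  const double cy = (py - oy) / sy - 0.5;
  const double cx = (px - ox) / sx - 0.5;
  if (cz < -1 || cz > nz || cy < -1 || cy > ny || cx < -1 || cx > nx) return 0.0;
  const int z0 = (int)std::floor(cz), y0 = (int)std::floor(cy), x0 = (int)std::floor(cx);
  const double fz = cz - z0, fy = cy - y0, fx = cx - x0;
  double acc = 0.0;
  for (int dx = 0; dx <= 1; ++dx)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dz = 0; dz <= 1; ++dz) {
        const int zz = z0 + dz, yy = y0 + dy, xx = x0 + dx;
        double v = 0.0;
        if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
          v = mask[lidx(zz, yy, xx, nz, ny)] ? 1.0 : 0.0;
        const double w = (dz ? fz : 1 - fz) * (dy ? fy : 1 - fy) * (dx ? fx : 1 - fx);
        acc += v * w;
      }
  return acc;
}

// distance (um) along dir from p to the 0.5-level boundary; NA if none in reach
static double ray_to_boundary(const LogicalVector& mask, int nz, int ny, int nx,
                              double sz, double sy, double sx,
                              double oz, double oy, double ox,
                              double pz, double py, double px,
                              double dz, double dy, double dx,
                              double step, double max_ray) {
  double prev_s = 0.0;
  double prev_v = sample_tri(mask, nz, ny, nx, sz, sy, sx, oz, oy, ox, pz, py, px);
  if (prev_v < 0.5) return 0.0;  // already at/over the boundary
  for (double s = step; s <= max_ray + 1e-9; s += step) {
    const double v = sample_tri(mask, nz, ny, nx, sz, sy, sx, oz, oy, ox,
                                pz + s * dz, py + s * dy, px + s * dx);
    if (v < 0.5) {
      // linear sub-step interpolation of the 0.5 crossing
      const double t = (prev_v - 0.5) / (prev_v - v);
      return prev_s + t * (s - prev_s);
    }
    prev_s = s;
    prev_v = v;
  }
  return NA_REAL;
}

// Rayburst-style local diameters at a set of centreline points.
// points / tangents: n x 3 matrices, (z, y, x) um. aggregate: 0 = median chord,
// 1 = min chord. Returns NA where the point is outside the mask or every
// opposed ray pair is unbounded within max_ray.
// [[Rcpp::export]]
NumericVector cpp_ray_diameters(LogicalVector mask, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix points, NumericMatrix tangents,
                                int n_rays, double step_um, double max_ray_um,
                                int aggregate) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const double oz = origin[0], oy = origin[1], ox = origin[2];
  const int n = points.nrow();
  const int half = n_rays / 2;
  NumericVector out(n, NA_REAL);
  std::vector<double> chords;
  for (int i = 0; i < n; ++i) {
    double tz = tangents(i, 0), ty = tangents(i, 1), tx = tangents(i, 2);
    double norm = std::sqrt(tz * tz + ty * ty + tx * tx);
    if (norm < 1e-12) continue;
    tz /= norm; ty /= norm; tx /= norm;
    // deterministic orthonormal frame: e = axis least aligned with tangent
    double ez = 0, ey = 0, ex = 0;
    const double az = std::fabs(tz), ay = std::fabs(ty), ax = std::fabs(tx);
    if (az <= ay && az <= ax) ez = 1; else if (ay <= ax) ey = 1; else ex = 1;
    double uz = ty * ex - tx * ey, uy = tx * ez - tz * ex, ux = tz * ey - ty * ez;
    norm = std::sqrt(uz * uz + uy * uy + ux * ux);
    uz /= norm; uy /= norm; ux /= norm;
    const double vz = ty * ux - tx * uy, vy = tx * uz - tz * ux, vx = tz * uy - ty * uz;

    const double pz = points(i, 0), py = points(i, 1), px = points(i, 2);
    if (sample_tri(mask, nz, ny, nx, sz, sy, sx, oz, oy, ox, pz, py, px) < 0.5)
      continue;  // point not inside foreground
    std::vector<double> b(n_rays, NA_REAL);
    for (int j = 0; j < n_rays; ++j) {
      const double th = 2.0 * M_PI * j / n_rays;
      const double dz = std::cos(th) * uz + std::sin(th) * vz;
      const double dy = std::cos(th) * uy + std::sin(th) * vy;
      const double dx = std::cos(th) * ux + std::sin(th) * vx;
      b[j] = ray_to_boundary(mask, nz, ny, nx, sz, sy, sx, oz, oy, ox,
                             pz, py, px, dz, dy, dx, step_um, max_ray_um);
    }
    chords.clear();
    for (int j = 0; j < half; ++j) {
      if (ISNA(b[j]) || ISNA(b[j + half])) continue;
      chords.push_back(b[j] + b[j + half]);
    }
    if (chords.empty()) continue;
    if (aggregate == 1) {
      out[i] = *std::min_element(chords.begin(), chords.end());
    } else {
      std::sort(chords.begin(), chords.end());
      size_t m = chords.size();
      if (aggregate == 2) m = (m + 1) / 2;  // lower band: chords below the median
      out[i] = (m % 2) ? chords[m / 2] : 0.5 * (chords[m / 2 - 1] + chords[m / 2]);
    }
  }
  return out;
}

// ----------------------------------------------------------- rasterizing ----

// Stamp a rounded cone ("capsule") between two points into a logical mask.
// p0/p1 (z,y,x) um; radius interpolated linearly along the segment.
// [[Rcpp::export]]
void cpp_stamp_capsule(LogicalVector mask, IntegerVector dim,
                       NumericVector spacing, NumericVector origin,
                       NumericVector p0, NumericVector p1,
                       double r0, double r1) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const double oz = origin[0], oy = origin[1], ox = origin[2];
  const double rmax = std::max(r0, r1);
  // bounding box in voxel indices
  const double lo[3] = {std::min(p0[0], p1[0]) - rmax, std::min(p0[1], p1[1]) - rmax,
                        std::min(p0[2], p1[2]) - rmax};
  const double hi[3] = {std::max(p0[0], p1[0]) + rmax, std::max(p0[1], p1[1]) + rmax,
                        std::max(p0[2], p1[2]) + rmax};
  const int z0 = std::max(0, (int)std::floor((lo[0] - oz) / sz - 0.5));
  const int z1 = std::min(nz - 1, (int)std::ceil((hi[0] - oz) / sz - 0.5));
  const int y0 = std::max(0, (int)std::floor((lo[1] - oy) / sy - 0.5));
  const int y1 = std::min(ny - 1, (int)std::ceil((hi[1] - oy) / sy - 0.5));
  const int x0 = std::max(0, (int)std::floor((lo[2] - ox) / sx - 0.5));
  const int x1 = std::min(nx - 1, (int)std::ceil((hi[2] - ox) / sx - 0.5));
  const double vz = p1[0] - p0[0], vy = p1[1] - p0[1], vx = p1[2] - p0[2];
  const double L2 = vz * vz + vy * vy + vx * vx;
  for (int x = x0; x <= x1; ++x) {
    const double wx = ox + (x + 0.5) * sx - p0[2];
    for (int y = y0; y <= y1; ++y) {
      const double wy = oy + (y + 0.5) * sy - p0[1];
      for (int z = z0; z <= z1; ++z) {
        const double wz = oz + (z + 0.5) * sz - p0[0];
        double t = 0.0;
        if (L2 > 0) t = std::max(0.0, std::min(1.0, (wz * vz + wy * vy + wx * vx) / L2));
        const double dz = wz - t * vz, dy = wy - t * vy, dx = wx - t * vx;
        const double r = r0 + t * (r1 - r0);
        if (dz * dz + dy * dy + dx * dx <= r * r)
          mask[lidx(z, y, x, nz, ny)] = true;
      }
    }
  }
}

// Mean-pool by integer factors per axis; partial edge blocks average the
// voxels available.
// [[Rcpp::export]]
NumericVector cpp_pool_mean(NumericVector vol, IntegerVector dim, IntegerVector factor) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int fz = factor[0], fy = factor[1], fx = factor[2];
  const int mz = (nz + fz - 1) / fz, my = (ny + fy - 1) / fy, mx = (nx + fx - 1) / fx;
  NumericVector out((xlen)mz * my * mx);
  out.attr("dim") = IntegerVector::create(mz, my, mx);
  for (int x = 0; x < mx; ++x)
    for (int y = 0; y < my; ++y)
      for (int z = 0; z < mz; ++z) {
        double acc = 0.0;
        int cnt = 0;
        for (int dx = 0; dx < fx; ++dx) {
          const int xx = x * fx + dx;
          if (xx >= nx) break;
          for (int dy = 0; dy < fy; ++dy) {
            const int yy = y * fy + dy;
            if (yy >= ny) break;
            for (int dz = 0; dz < fz; ++dz) {
              const int zz = z * fz + dz;
              if (zz >= nz) break;
              acc += vol[lidx(zz, yy, xx, nz, ny)];
              ++cnt;
            }
          }
        }
        out[lidx(z, y, x, mz, my)] = acc / cnt;
      }
  return out;
}
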