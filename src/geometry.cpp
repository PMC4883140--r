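#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Arrays use dim = (nz, ny, nx), column-major (z fastest), like dijkstra.cpp.

namespace {

inline double clamp01(double t) { return t < 0 ? 0 : (t > 1 ? 1 : t); }

}  // namespace

// Minimum Euclidean distance from each voxel center to a polyline, updated
// into `field` (a copy is returned). Only voxels within `maxdist` of some
// polyline segment's bounding capsule are touched, so the cost is local to
// the polyline. `pts` is m x 3 of 1-based (z, y, x) voxel coordinates.
// [[Rcpp::export]]
NumericVector cpp_polyline_dist(NumericVector field, IntegerVector dims,
                                NumericMatrix pts, double maxdist) {
  NumericVector out = clone(field);
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int m = pts.nrow();
  if (m == 0) return out;
  for (int s = 0; s < std::max(1, m - 1); ++s) {
    const int s2 = (m == 1) ? 0 : s + 1;
    const double az = pts(s, 0) - 1, ay = pts(s, 1) - 1, ax = pts(s, 2) - 1;
    const double bz = pts(s2, 0) - 1, by = pts(s2, 1) - 1, bx = pts(s2, 2) - 1;
    const double vz = bz - az, vy = by - ay, vx = bx - ax;
    const double vv = vz * vz + vy * vy + vx * vx;
    const int z0 = std::max(0, (int)std::floor(std::min(az, bz) - maxdist));
    const int z1 = std::min(nz - 1, (int)std::ceil(std::max(az, bz) + maxdist));
    const int y0 = std::max(0, (int)std::floor(std::min(ay, by) - maxdist));
    const int y1 = std::min(ny - 1, (int)std::ceil(std::max(ay, by) + maxdist));
    const int x0 = std::max(0, (int)std::floor(std::min(ax, bx) - maxdist));
    const int x1 = std::min(nx - 1, (int)std::ceil(std::max(ax, bx) + maxdist));
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          const double wz = z - az, wy = y - ay, wx = x - ax;
          const double t = vv > 0 ? clamp01((wz * vz + wy * vy + wx * vx) / vv) : 0.0;
          const double dz_ = wz - t * vz, dy_ = wy - t * vy, dx_ = wx - t * vx;
          const double d = std::sqrt(dz_ * dz_ + dy_ * dy_ + dx_ * dx_);
          const size_t idx = z + (size_t)nz * (y + (size_t)ny * x);
          if (d < out[idx]) out[idx] = d;
        }
  }
  return out;
}

// Arc-length position (along the polyline) of the closest polyline point for
// each voxel within maxdist; voxels further away get NA. Used to carve gaps
// at prescribed arc-length intervals.
// [[Rcpp::export]]
List cpp_polyline_dist_arc(IntegerVector dims, NumericMatrix pts,
                           double maxdist) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const size_t n = (size_t)nz * ny * nx;
  NumericVector dist(n, R_PosInf), arc(n, NA_REAL);
  const int m = pts.nrow();
  std::vector<double> cum(m, 0.0);
  for (int s = 1; s < m; ++s) {
    const double dz_ = pts(s, 0) - pts(s - 1, 0);
    const double dy_ = pts(s, 1) - pts(s - 1, 1);
    const double dx_ = pts(s, 2) - pts(s - 1, 2);
    cum[s] = cum[s - 1] + std::sqrt(dz_ * dz_ + dy_ * dy_ + dx_ * dx_);
  }
  for (int s = 0; s < std::max(1, m - 1); ++s) {
    const int s2 = (m == 1) ? 0 : s + 1;
    const double az = pts(s, 0) - 1, ay = pts(s, 1) - 1, ax = pts(s, 2) - 1;
    const double bz = pts(s2, 0) - 1, by = pts(s2, 1) - 1, bx = pts(s2, 2) - 1;
    const double vz = bz - az, vy = by - ay, vx = bx - ax;
    const double vv = vz * vz + vy * vy + vx * vx;
    const double seglen = std::sqrt(vv);
    const int z0 = std::max(0, (int)std::floor(std::min(az, bz) - maxdist));
    const int z1 = std::min(nz - 1, (int)std::ceil(std::max(az, bz) + maxdist));
    const int y0 = std::max(0, (int)std::floor(std::min(ay, by) - maxdist));
    const int y1 = std::min(ny - 1, (int)std::ceil(std::max(ay, by) + maxdist));
    const int x0 = std::max(0, (int)std::floor(std::min(ax, bx) - maxdist));
    const int x1 = std::min(nx - 1, (int)std::ceil(std::max(ax, bx) + maxdist));
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          const double wz = z - az, wy = y - ay, wx = x - ax;
          const double t = vv > 0 ? clamp01((wz * vz + wy * vy + wx * vx) / vv) : 0.0;
          const double dz_ = wz - t * vz, dy_ = wy - t * vy, dx_ = wx - t * vx;
          const double d = std::sqrt(dz_ * dz_ + dy_ * dy_ + dx_ * dx_);
          const size_t idx = z + (size_t)nz * (y + (size_t)ny * x);
          if (d < dist[idx]) {
            dist[idx] = d;
            arc[idx] = cum[s] + t * seglen;
          }
        }
  }
  return List::create(_["dist"] = dist, _["arc"] = arc);
}

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// distance of every voxel to the nearest TRUE voxel of `feature`.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const size_t n = (size_t)nz * ny * nx;
  const double INF = 1e20;
  std::vector<double> f(n);
  for (size_t i = 0; i < n; ++i) f[i] = feature[i] ? 0.0 : INF;

  const int maxdim = std::max(nz, std::max(ny, nx));
  std::vector<double> d(maxdim), zbuf(maxdim + 1), fw(maxdim);
  std::vector<int> v(maxdim);

  // 1D squared-distance lower envelope
  auto dt1 = [&](int len, size_t start, size_t stride) {
    for (int q = 0; q < len; ++q) fw[q] = f[start + stride * q];
    int k = 0;
    v[0] = 0; zbuf[0] = -INF; zbuf[1] = INF;
    for (int q = 1; q < len; ++q) {
      double s = ((fw[q] + q * q) - (fw[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      while (s <= zbuf[k]) {
        --k;
        s = ((fw[q] + q * q) - (fw[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      }
      ++k; v[k] = q; zbuf[k] = s; zbuf[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < len; ++q) {
      while (zbuf[k + 1] < q) ++k;
      d[q] = (q - v[k]) * (double)(q - v[k]) + fw[v[k]];
    }
    for (int q = 0; q < len; ++q) f[start + stride * q] = d[q];
  };

  for (int x = 0; x < nx; ++x)  // along z
    for (int y = 0; y < ny; ++y)
      dt1(nz, (size_t)nz * (y + (size_t)ny * x), 1);
  for (int x = 0; x < nx; ++x)  // along y
    for (int z = 0; z < nz; ++z)
      dt1(ny, z + (size_t)nz * (size_t)ny * x, nz);
  for (int y = 0; y < ny; ++y)  // along x
    for (int z = 0; z < nz; ++z)
      dt1(nx, z + (size_t)nz * y, (size_t)nz * ny);

  return NumericVector(f.begin(), f.end());
}

// Mark voxels within per-point radii of a set of points (spheres; with points
// spaced <= 1 voxel apart along a path this stamps a capsule).
// pts: m x 3 of 1-based (z,y,x). Returns updated copy of `covered`.
// [[Rcpp::export]]
LogicalVector cpp_stamp_spheres(LogicalVector covered, IntegerVector dims,
                                NumericMatrix pts, NumericVector radii) {
  LogicalVector out = clone(covered);
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  for (int s = 0; s < pts.nrow(); ++s) {
    const double cz = pts(s, 0) - 1, cy = pts(s, 1) - 1, cx = pts(s, 2) - 1;
    const double r = radii[s % radii.size()], r2 = r * r;
    const int z0 = std::max(0, (int)std::floor(cz - r));
    const int z1 = std::min(nz - 1, (int)std::ceil(cz + r));
    const int y0 = std::max(0, (int)std::floor(cy - r));
    const int y1 = std::min(ny - 1, (int)std::ceil(cy + r));
    const int x0 = std::max(0, (int)std::floor(cx - r));
    const int x1 = std::min(nx - 1, (int)std::ceil(cx + r));
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          const double dz_ = z - cz, dy_ = y - cy, dx_ = x - cx;
          if (dz_ * dz_ + dy_ * dy_ + dx_ * dx_ <= r2)
            out[z + (size_t)nz * (y + (size_t)ny * x)] = true;
        }
  }
  return out;
}
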