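// Spatial query kernels: uniform-grid nearest-neighbour search over point
// clouds (signed-distance evaluation, bilateral normal smoothing) and
// ray-triangle casting for the shape diameter function. Geometry is world mm.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

namespace {

struct UniformGrid {
  double lo[3];
  double h;
  int dims[3];
  std::vector<int> cell_start;   // size ncells+1
  std::vector<int> order;        // point ids sorted by cell
  const NumericMatrix& pts;

  UniformGrid(const NumericMatrix& p, double target_per_cell) : pts(p) {
    const int n = p.nrow();
    double hi[3];
    for (int a = 0; a < 3; ++a) { lo[a] = R_PosInf; hi[a] = R_NegInf; }
    for (int i = 0; i < n; ++i)
      for (int a = 0; a < 3; ++a) {
        lo[a] = std::min(lo[a], p(i, a));
        hi[a] = std::max(hi[a], p(i, a));
      }
    double vol = 1.0;
    for (int a = 0; a < 3; ++a) vol *= std::max(hi[a] - lo[a], 1e-9);
    h = std::cbrt(vol * target_per_cell / std::max(n, 1));
    if (!(h > 0) || !R_finite(h)) h = 1.0;
    long ncells = 1;
    for (int a = 0; a < 3; ++a) {
      dims[a] = std::max(1, (int)std::floor((hi[a] - lo[a]) / h) + 1);
      ncells *= dims[a];
      if (ncells > 50000000L) { // degenerate aspect: coarsen
        h *= 2.0; a = -1; ncells = 1;
      }
    }
    std::vector<int> cnt((size_t)dims[0] * dims[1] * dims[2] + 1, 0);
    std::vector<int> cid(n);
    for (int i = 0; i < n; ++i) {
      cid[i] = cell_of(p(i, 0), p(i, 1), p(i, 2));
      cnt[cid[i] + 1]++;
    }
    for (size_t c = 1; c < cnt.size(); ++c) cnt[c] += cnt[c - 1];
    cell_start = cnt;
    order.resize(n);
    std::vector<int> fill(cnt.begin(), cnt.end());
    for (int i = 0; i < n; ++i) order[fill[cid[i]]++] = i;
  }

  int clampi(int v, int m) const { return std::max(0, std::min(v, m - 1)); }

  int cell_of(double x, double y, double z) const {
    int ix = clampi((int)std::floor((x - lo[0]) / h), dims[0]);
    int iy = clampi((int)std::floor((y - lo[1]) / h), dims[1]);
    int iz = clampi((int)std::floor((z - lo[2]) / h), dims[2]);
    return ix + dims[0] * (iy + dims[1] * iz);
  }

  // nearest point id to (x,y,z); expanding shell search
  int nearest(double x, double y, double z, double* dist_out) const {
    int cx = clampi((int)std::floor((x - lo[0]) / h), dims[0]);
    int cy = clampi((int)std::floor((y - lo[1]) / h), dims[1]);
    int cz = clampi((int)std::floor((z - lo[2]) / h), dims[2]);
    double best = std::numeric_limits<double>::infinity();
    int best_id = -1;
    int maxdim = std::max(dims[0], std::max(dims[1], dims[2]));
    for (int ring = 0; ring <= maxdim; ++ring) {
      if (best_id >= 0 && best <= (double)(ring - 1) * h) break;
      for (int iz = cz - ring; iz <= cz + ring; ++iz) {
        if (iz < 0 || iz >= dims[2]) continue;
        for (int iy = cy - ring; iy <= cy + ring; ++iy) {
          if (iy < 0 || iy >= dims[1]) continue;
          for (int ix = cx - ring; ix <= cx + ring; ++ix) {
            if (ix < 0 || ix >= dims[0]) continue;
            // only the shell, not the filled cube
            if (ring > 0 && std::abs(ix - cx) != ring &&
                std::abs(iy - cy) != ring && std::abs(iz - cz) != ring)
              continue;
            int c = ix + dims[0] * (iy + dims[1] * iz);
            for (int k = cell_start[c]; k < cell_start[c + 1]; ++k) {
              int i = order[k];
              double dx = pts(i, 0) - x, dy = pts(i, 1) - y, dz = pts(i, 2) - z;
              double d = std::sqrt(dx * dx + dy * dy + dz * dz);
              if (d < best) { best = d; best_id = i; }
            }
          }
        }
      }
    }
    *dist_out = best;
    return best_id;
  }

  // collect point ids within radius r of (x,y,z)
  void within(double x, double y, double z, double r,
              std::vector<int>& out) const {
    out.clear();
    int x0 = clampi((int)std::floor((x - r - lo[0]) / h), dims[0]);
    int x1 = clampi((int)std::floor((x + r - lo[0]) / h), dims[0]);
    int y0 = clampi((int)std::floor((y - r - lo[1]) / h), dims[1]);
    int y1 = clampi((int)std::floor((y + r - lo[1]) / h), dims[1]);
    int z0 = clampi((int)std::floor((z - r - lo[2]) / h), dims[2]);
    int z1 = clampi((int)std::floor((z + r - lo[2]) / h), dims[2]);
    double r2 = r * r;
    for (int iz = z0; iz <= z1; ++iz)
      for (int iy = y0; iy <= y1; ++iy)
        for (int ix = x0; ix <= x1; ++ix) {
          int c = ix + dims[0] * (iy + dims[1] * iz);
          for (int k = cell_start[c]; k < cell_start[c + 1]; ++k) {
            int i = order[k];
            double dx = pts(i, 0) - x, dy = pts(i, 1) - y, dz = pts(i, 2) - z;
            if (dx * dx + dy * dy + dz * dz <= r2) out.push_back(i);
          }
        }
  }
};

}  // namespace

// Signed distance from each query point to the oriented point cloud:
// distance to the nearest surfel, signed by that surfel's normal
// (positive outside).
// [[Rcpp::export]]
NumericVector cpp_signed_distance(NumericMatrix query, NumericMatrix pts,
                                  NumericMatrix normals) {
  UniformGrid grid(pts, 4.0);
  const int nq = query.nrow();
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double dist;
    int i = grid.nearest(query(q, 0), query(q, 1), query(q, 2), &dist);
    double dx = query(q, 0) - pts(i, 0);
    double dy = query(q, 1) - pts(i, 1);
    double dz = query(q, 2) - pts(i, 2);
    double s = dx * normals(i, 0) + dy * normals(i, 1) + dz * normals(i, 2);
    out[q] = (s >= 0) ? dist : -dist;
  }
  return out;
}

// Index (1-based) of the nearest reference point for each query point.
// [[Rcpp::export]]
IntegerVector cpp_nearest_index(NumericMatrix query, NumericMatrix pts) {
  UniformGrid grid(pts, 4.0);
  const int nq = query.nrow();
  IntegerVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double dist;
    out[q] = grid.nearest(query(q, 0), query(q, 1), query(q, 2), &dist) + 1;
  }
  return out;
}

// One pass of bilateral normal smoothing: each normal becomes the
// renormalized sum of neighbour normals within `radius`, weighted by a
// spatial Gaussian (sigma_s) and a normal-similarity Gaussian (sigma_n on
// 1 - dot(ni, nj)).
// [[Rcpp::export]]
NumericMatrix cpp_smooth_normals(NumericMatrix pts, NumericMatrix normals,
                                 double radius, double sigma_s,
                                 double sigma_n) {
  UniformGrid grid(pts, 4.0);
  const int n = pts.nrow();
  NumericMatrix out(n, 3);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    grid.within(pts(i, 0), pts(i, 1), pts(i, 2), radius, nb);
    double ax = 0, ay = 0, az = 0;
    for (size_t k = 0; k < nb.size(); ++k) {
      int j = nb[k];
      double dx = pts(j, 0) - pts(i, 0);
      double dy = pts(j, 1) - pts(i, 1);
      double dz = pts(j, 2) - pts(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double dot = normals(i, 0) * normals(j, 0) +
                   normals(i, 1) * normals(j, 1) +
                   normals(i, 2) * normals(j, 2);
      if (dot <= 0) continue;  // opposing side of a thin tube: skip
      double w = std::exp(-d2 / (2 * sigma_s * sigma_s)) *
                 std::exp(-(1 - dot) * (1 - dot) / (2 * sigma_n * sigma_n));
      ax += w * normals(j, 0);
      ay += w * normals(j, 1);
      az += w * normals(j, 2);
    }
    double nn = std::sqrt(ax * ax + ay * ay + az * az);
    if (nn < 1e-12) {
      out(i, 0) = normals(i, 0); out(i, 1) = normals(i, 1); out(i, 2) = normals(i, 2);
    } else {
      out(i, 0) = ax / nn; out(i, 1) = ay / nn; out(i, 2) = az / nn;
    }
  }
  return out;
}

// First-hit distances for a batch of rays against a triangle soup
// (Moller-Trumbore). Hits closer than `eps` along the ray are ignored.
// Returns Inf where a ray misses everything.
// [[Rcpp::export]]
NumericVector cpp_raycast(NumericMatrix V, IntegerMatrix F,
                          NumericMatrix origins, NumericMatrix dirs,
                          double eps) {
  const int nf = F.nrow();
  const int nr = origins.nrow();
  NumericVector out(nr, R_PosInf);
  std::vector<double> v0(nf * 3), e1(nf * 3), e2(nf * 3);
  for (int f = 0; f < nf; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    for (int k = 0; k < 3; ++k) {
      v0[f * 3 + k] = V(a, k);
      e1[f * 3 + k] = V(b, k) - V(a, k);
      e2[f * 3 + k] = V(c, k) - V(a, k);
    }
  }
  for (int r = 0; r < nr; ++r) {
    double ox = origins(r, 0), oy = origins(r, 1), oz = origins(r, 2);
    double dx = dirs(r, 0), dy = dirs(r, 1), dz = dirs(r, 2);
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      const double* a = &v0[f * 3];
      const double* u = &e1[f * 3];
      const double* w = &e2[f * 3];
      // p = dir x e2
      double px = dy * w[2] - dz * w[1];
      double py = dz * w[0] - dx * w[2];
      double pz = dx * w[1] - dy * w[0];
      double det = u[0] * px + u[1] * py + u[2] * pz;
      if (std::fabs(det) < 1e-12) continue;
      double inv = 1.0 / det;
      double tx = ox - a[0], ty = oy - a[1], tz = oz - a[2];
      double uu = (tx * px + ty * py + tz * pz) * inv;
      if (uu < -1e-9 || uu > 1 + 1e-9) continue;
      double qx = ty * u[2] - tz * u[1];
      double qy = tz * u[0] - tx * u[2];
      double qz = tx * u[1] - ty * u[0];
      double vv = (dx * qx + dy * qy + dz * qz) * inv;
      if (vv < -1e-9 || uu + vv > 1 + 1e-9) continue;
      double t = (w[0] * qx + w[1] * qy + w[2] * qz) * inv;
      if (t > eps && t < best) best = t;
    }
    out[r] = best;
  }
  return out;
}
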