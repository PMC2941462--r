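#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

// Uniform-grid cell list for fixed-radius neighbor queries.
struct CellList {
  double cell;
  double ox, oy, oz;
  int nx, ny, nz;
  std::unordered_map<int64_t, std::vector<int>> cells;

  CellList(const NumericMatrix& pts, double cell_size) : cell(cell_size) {
    ox = oy = oz = R_PosInf;
    for (int i = 0; i < pts.nrow(); ++i) {
      ox = std::min(ox, pts(i, 0));
      oy = std::min(oy, pts(i, 1));
      oz = std::min(oz, pts(i, 2));
    }
    for (int i = 0; i < pts.nrow(); ++i)
      cells[key(pts(i, 0), pts(i, 1), pts(i, 2))].push_back(i);
  }
  int64_t key(double x, double y, double z) const {
    int64_t ix = (int64_t)std::floor((x - ox) / cell);
    int64_t iy = (int64_t)std::floor((y - oy) / cell);
    int64_t iz = (int64_t)std::floor((z - oz) / cell);
    return (ix << 42) ^ (iy << 21) ^ iz;
  }
  template <typename F>
  void around(double x, double y, double z, F f) const {
    int64_t ix = (int64_t)std::floor((x - ox) / cell);
    int64_t iy = (int64_t)std::floor((y - oy) / cell);
    int64_t iz = (int64_t)std::floor((z - oz) / cell);
    for (int64_t dx = -1; dx <= 1; ++dx)
      for (int64_t dy = -1; dy <= 1; ++dy)
        for (int64_t dz = -1; dz <= 1; ++dz) {
          int64_t k = ((ix + dx) << 42) ^ ((iy + dy) << 21) ^ (iz + dz);
          auto it = cells.find(k);
          if (it == cells.end()) continue;
          for (int j : it->second) f(j);
        }
  }
};

// Keep surface candidate points not strictly inside any other atom's
// inflated sphere.  pts: candidate points; parent: 1-based atom index that
// generated each point; centers/radii: inflated atom spheres.
// [[Rcpp::export(name = ".cpp_prune_buried")]]
LogicalVector cpp_prune_buried(NumericMatrix pts, IntegerVector parent,
                               NumericMatrix centers, NumericVector radii) {
  double rmax = 0.0;
  for (int j = 0; j < radii.size(); ++j) rmax = std::max(rmax, radii[j]);
  CellList cl(centers, rmax > 0 ? rmax : 1.0);
  LogicalVector keep(pts.nrow(), true);
  const double tol = 1e-6;
  for (int i = 0; i < pts.nrow(); ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    int par = parent[i] - 1;
    bool buried = false;
    cl.around(x, y, z, [&](int j) {
      if (buried || j == par) return;
      double dx = x - centers(j, 0), dy = y - centers(j, 1), dz = z - centers(j, 2);
      double r = radii[j] - tol;
      if (dx * dx + dy * dy + dz * dz < r * r) buried = true;
    });
    keep[i] = !buried;
  }
  return keep;
}

// Solve the 4x4 system M u = b by Gaussian elimination with partial
// pivoting; returns false when near-singular (pivot ratio beyond cond_tol).
static bool solve4(double M[4][4], double b[4], double u[4], double cond_tol) {
  int idx[4] = {0, 1, 2, 3};
  double pmax = 0.0, pmin = R_PosInf;
  for (int col = 0; col < 4; ++col) {
    int piv = col;
    for (int r = col + 1; r < 4; ++r)
      if (std::fabs(M[idx[r]][col]) > std::fabs(M[idx[piv]][col])) piv = r;
    std::swap(idx[col], idx[piv]);
    double p = M[idx[col]][col];
    if (std::fabs(p) < 1e-12) return false;
    pmax = std::max(pmax, std::fabs(p));
    pmin = std::min(pmin, std::fabs(p));
    for (int r = col + 1; r < 4; ++r) {
      double f = M[idx[r]][col] / p;
      for (int c = col; c < 4; ++c) M[idx[r]][c] -= f * M[idx[col]][c];
      b[idx[r]] -= f * b[idx[col]];
    }
  }
  if (pmax / pmin > cond_tol) return false;
  for (int col = 3; col >= 0; --col) {
    double s = b[idx[col]];
    for (int c = col + 1; c < 4; ++c) s -= M[idx[col]][c] * u[c];
    u[col] = s / M[idx[col]][col];
  }
  return true;
}

// Per-point algebraic (Coope) least-squares sphere fit over the patch of
// envelope points within patch_radius.  Returns theta (signed radius:
// positive when the fitted center lies on the outward-normal, i.e.
// solvent, side), a status column (1 = fitted, 0 = degenerate or
// under-populated patch), and the RMS residual of the best-fit *plane*
// through the patch (regression of the normal component on the two tangent
// coordinates): a patch a plane explains to within sampling ripple is flat
// regardless of what radius the sphere fit locks onto.  Patch coordinates
// are centered on the query point for conditioning.
// [[Rcpp::export(name = ".cpp_fit_spheres")]]
NumericMatrix cpp_fit_spheres(NumericMatrix pts, NumericMatrix normals,
                              NumericVector patch_radius, int min_points,
                              double cond_tol) {
  int n = pts.nrow();
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, patch_radius[i]);
  CellList cl(pts, rmax > 0 ? rmax : 1.0);
  NumericMatrix out(n, 3);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    double r2 = patch_radius[i] * patch_radius[i];
    nb.clear();
    cl.around(x, y, z, [&](int j) {
      double dx = pts(j, 0) - x, dy = pts(j, 1) - y, dz = pts(j, 2) - z;
      if (dx * dx + dy * dy + dz * dz <= r2) nb.push_back(j);
    });
    if ((int)nb.size() < min_points) {
      out(i, 0) = NA_REAL; out(i, 1) = 0; out(i, 2) = 0;
      continue;
    }
    // plane residual in the local normal frame: w ~ a + b u + c v
    double nx = normals(i, 0), ny = normals(i, 1), nz = normals(i, 2);
    double ax = std::fabs(nx) < 0.9 ? 1.0 : 0.0;
    double ay = std::fabs(nx) < 0.9 ? 0.0 : 1.0;
    double t1x = ny * 0 - nz * ay, t1y = nz * ax - nx * 0, t1z = nx * ay - ny * ax;
    double t1n = std::sqrt(t1x * t1x + t1y * t1y + t1z * t1z);
    t1x /= t1n; t1y /= t1n; t1z /= t1n;
    double t2x = ny * t1z - nz * t1y, t2y = nz * t1x - nx * t1z,
           t2z = nx * t1y - ny * t1x;
    double P[3][3] = {{0}}, q[3] = {0};
    double sww = 0.0;
    for (int j : nb) {
      double px = pts(j, 0) - x, py = pts(j, 1) - y, pz = pts(j, 2) - z;
      double uu = px * t1x + py * t1y + pz * t1z;
      double vv = px * t2x + py * t2y + pz * t2z;
      double ww = px * nx + py * ny + pz * nz;
      double row[3] = {1.0, uu, vv};
      for (int r = 0; r < 3; ++r) {
        for (int c = 0; c < 3; ++c) P[r][c] += row[r] * row[c];
        q[r] += row[r] * ww;
      }
      sww += ww * ww;
    }
    // 3x3 solve by Cramer with fallback to zero coefficients
    double det =
      P[0][0] * (P[1][1] * P[2][2] - P[1][2] * P[2][1]) -
      P[0][1] * (P[1][0] * P[2][2] - P[1][2] * P[2][0]) +
      P[0][2] * (P[1][0] * P[2][1] - P[1][1] * P[2][0]);
    double rms_plane;
    if (std::fabs(det) < 1e-10) {
      rms_plane = std::sqrt(sww / nb.size());
    } else {
      auto det3 = [&](int col) {
        double A[3][3];
        for (int r = 0; r < 3; ++r)
          for (int c = 0; c < 3; ++c) A[r][c] = (c == col) ? q[r] : P[r][c];
        return A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
               A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
               A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
      };
      double a = det3(0) / det, bb = det3(1) / det, cc = det3(2) / det;
      // SSE = sum w^2 - coef . q
      double sse = sww - (a * q[0] + bb * q[1] + cc * q[2]);
      rms_plane = std::sqrt(std::max(0.0, sse) / nb.size());
    }
    out(i, 2) = rms_plane;

    // normal equations for [2x 2y 2z 1] u = x^2+y^2+z^2, local coords
    double M[4][4] = {{0}}, b[4] = {0};
    for (int j : nb) {
      double px = pts(j, 0) - x, py = pts(j, 1) - y, pz = pts(j, 2) - z;
      double row[4] = {2 * px, 2 * py, 2 * pz, 1.0};
      double f = px * px + py * py + pz * pz;
      for (int r = 0; r < 4; ++r) {
        for (int c = 0; c < 4; ++c) M[r][c] += row[r] * row[c];
        b[r] += row[r] * f;
      }
    }
    double u[4];
    if (!solve4(M, b, u, cond_tol)) {
      out(i, 0) = NA_REAL; out(i, 1) = 0;
      continue;
    }
    double R2 = u[3] + u[0] * u[0] + u[1] * u[1] + u[2] * u[2];
    if (R2 <= 0) {
      out(i, 0) = NA_REAL; out(i, 1) = 0;
      continue;
    }
    double R = std::sqrt(R2);
    double s = u[0] * normals(i, 0) + u[1] * normals(i, 1) + u[2] * normals(i, 2);
    out(i, 0) = (s >= 0 ? R : -R);
    out(i, 1) = 1;
  }
  return out;
}
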