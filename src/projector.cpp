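#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact per-material ray path lengths through a 2D material-weight grid,
// parallel-beam geometry. Siddon-style traversal: every voxel crossed by a
// ray contributes its exact chord length times the voxel's weight vector, so
// the projector's only error versus an analytic phantom is voxelization.
//
// Grid convention: cell (i, j), 0-based, is centered at
//   ((i - (nx-1)/2) * px, (j - (ny-1)/2) * py)
// relative to the rotation center; boundaries at (i - nx/2) * px.
// Ray for angle theta, detector coordinate u:
//   origin (u cos t, u sin t), direction (-sin t, cos t)
// which realizes p(theta, u) = integral of f over {x cos t + y sin t = u}.
//
// weights: nx * ny * nm array (column-major), angles in radians, dets in cm.
// Returns an (n_angles * n_dets) x nm matrix of path lengths in cm.
// [[Rcpp::export]]
NumericMatrix cpp_siddon_paths(NumericVector weights, int nx, int ny, int nm,
                               double px, double py,
                               NumericVector angles, NumericVector dets) {
  const int na = angles.size(), nd = dets.size();
  NumericMatrix out(na * nd, nm);
  const double xmin = -0.5 * nx * px, ymin = -0.5 * ny * py;
  const double xmax = -xmin, ymax = -ymin;
  const double eps = 1e-12;

  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    const double dx = -st, dy = ct;
    for (int d = 0; d < nd; ++d) {
      const double ox = dets[d] * ct, oy = dets[d] * st;
      // slab clipping against the bounding box
      double t0 = -1e30, t1 = 1e30;
      bool miss = false;
      if (std::fabs(dx) < eps) {
        if (ox < xmin || ox > xmax) miss = true;
      } else {
        double ta = (xmin - ox) / dx, tb = (xmax - ox) / dx;
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta); t1 = std::min(t1, tb);
      }
      if (std::fabs(dy) < eps) {
        if (oy < ymin || oy > ymax) miss = true;
      } else {
        double ta = (ymin - oy) / dy, tb = (ymax - oy) / dy;
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta); t1 = std::min(t1, tb);
      }
      if (miss || t1 <= t0) continue;

      // entry cell
      double t = t0;
      double xe = ox + t * dx, ye = oy + t * dy;
      int i = (int)std::floor((xe - xmin) / px);
      int j = (int)std::floor((ye - ymin) / py);
      if (i < 0) i = 0;
      if (i >= nx) i = nx - 1;
      if (j < 0) j = 0;
      if (j >= ny) j = ny - 1;

      const int stepi = dx > eps ? 1 : (dx < -eps ? -1 : 0);
      const int stepj = dy > eps ? 1 : (dy < -eps ? -1 : 0);
      const double tdx = stepi ? px / std::fabs(dx) : 1e30;
      const double tdy = stepj ? py / std::fabs(dy) : 1e30;
      double tmx, tmy;
      if (stepi > 0)      tmx = ((i + 1) * px + xmin - ox) / dx;
      else if (stepi < 0) tmx = (i * px + xmin - ox) / dx;
      else                tmx = 1e30;
      if (stepj > 0)      tmy = ((j + 1) * py + ymin - oy) / dy;
      else if (stepj < 0) tmy = (j * py + ymin - oy) / dy;
      else                tmy = 1e30;

      const int row = a * nd + d;
      while (t < t1 - eps) {
        double tnext = std::min(std::min(tmx, tmy), t1);
        double len = tnext - t;
        if (len > 0 && i >= 0 && i < nx && j >= 0 && j < ny) {
          const R_xlen_t base = (R_xlen_t)i + (R_xlen_t)nx * j;
          const R_xlen_t plane = (R_xlen_t)nx * ny;
          for (int m = 0; m < nm; ++m) {
            double w = weights[base + plane * m];
            if (w != 0.0) out(row, m) += len * w;
          }
        }
        t = tnext;
        if (tmx <= tmy) { i += stepi; tmx += tdx; }
        else            { j += stepj; tmy += tdy; }
        if (i < 0 || i >= nx || j < 0 || j >= ny) break;
      }
    }
  }
  return out;
}

// Backprojection of filtered parallel-beam projections onto a centered grid.
// q: n_angles x n_dets filtered sinogram; wtheta: per-angle angular weights;
// dets: detector coordinates (cm, ascending). Linear interpolation along the
// detector; rays falling outside the detector span contribute zero.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix q, NumericVector angles,
                              NumericVector wtheta, NumericVector dets,
                              int nx, int ny, double px, double py) {
  const int na = angles.size(), nd = dets.size();
  const double u0 = dets[0], du = (dets[nd - 1] - dets[0]) / (nd - 1);
  NumericMatrix img(nx, ny);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    const double w = wtheta[a];
    for (int j = 0; j < ny; ++j) {
      const double y = (j - (ny - 1) / 2.0) * py;
      for (int i = 0; i < nx; ++i) {
        const double x = (i - (nx - 1) / 2.0) * px;
        const double u = x * ct + y * st;
        const double f = (u - u0) / du;
        if (f < 0 || f > nd - 1) continue;
        int k = (int)std::floor(f);
        if (k >= nd - 1) k = nd - 2;
        const double frac = f - k;
        img(i, j) += w * ((1 - frac) * q(a, k) + frac * q(a, k + 1));
      }
    }
  }
  return img;
}
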