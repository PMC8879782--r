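#pragma once
#include <Rcpp.h>
#include <cmath>
#include <cstddef>

// Lightweight view of a 3D scalar raster in world coordinates.
// Voxel (i,j,k) (0-based) has its centre at origin + index * spacing.
// The interpolation support is the convex hull of voxel centres.
struct VolView {
  const double* v;
  int nx, ny, nz;
  double sx, sy, sz;
  double ox, oy, oz;

  inline double at(int i, int j, int k) const {
    return v[(std::size_t)i + (std::size_t)nx * ((std::size_t)j + (std::size_t)ny * k)];
  }
};

// Snap continuous indices that are within rounding noise of a grid plane
// onto it, so that e.g. an identity warp reproduces the input exactly even
// for non-dyadic voxel spacings.
inline double snap_idx(double g) {
  double r = std::floor(g + 0.5);
  return (std::fabs(g - r) < 1e-9) ? r : g;
}

// Trilinear interpolation with boundary clamping (samples outside the
// support take the nearest boundary value).
inline double tri_sample_clamped(const VolView& V, double x, double y, double z) {
  double gx = snap_idx((x - V.ox) / V.sx);
  double gy = snap_idx((y - V.oy) / V.sy);
  double gz = snap_idx((z - V.oz) / V.sz);
  if (gx < 0) gx = 0; else if (gx > V.nx - 1) gx = V.nx - 1;
  if (gy < 0) gy = 0; else if (gy > V.ny - 1) gy = V.ny - 1;
  if (gz < 0) gz = 0; else if (gz > V.nz - 1) gz = V.nz - 1;
  int i0 = (int)gx, j0 = (int)gy, k0 = (int)gz;
  if (i0 > V.nx - 2) i0 = V.nx > 1 ? V.nx - 2 : 0;
  if (j0 > V.ny - 2) j0 = V.ny > 1 ? V.ny - 2 : 0;
  if (k0 > V.nz - 2) k0 = V.nz > 1 ? V.nz - 2 : 0;
  double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  int i1 = V.nx > 1 ? i0 + 1 : i0;
  int j1 = V.ny > 1 ? j0 + 1 : j0;
  int k1 = V.nz > 1 ? k0 + 1 : k0;
  double c000 = V.at(i0, j0, k0), c100 = V.at(i1, j0, k0);
  double c010 = V.at(i0, j1, k0), c110 = V.at(i1, j1, k0);
  double c001 = V.at(i0, j0, k1), c101 = V.at(i1, j0, k1);
  double c011 = V.at(i0, j1, k1), c111 = V.at(i1, j1, k1);
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Exact spatial gradient (d/d world mm) of the clamped trilinear
// interpolant. Where a coordinate is clamped the corresponding
// derivative component is zero (the interpolant is constant there).
inline void tri_grad_clamped(const VolView& V, double x, double y, double z,
                             double* gout) {
  double gx = snap_idx((x - V.ox) / V.sx);
  double gy = snap_idx((y - V.oy) / V.sy);
  double gz = snap_idx((z - V.oz) / V.sz);
  bool cx = false, cy = false, cz = false;
  if (gx < 0) { gx = 0; cx = true; } else if (gx > V.nx - 1) { gx = V.nx - 1; cx = true; }
  if (gy < 0) { gy = 0; cy = true; } else if (gy > V.ny - 1) { gy = V.ny - 1; cy = true; }
  if (gz < 0) { gz = 0; cz = true; } else if (gz > V.nz - 1) { gz = V.nz - 1; cz = true; }
  int i0 = (int)gx, j0 = (int)gy, k0 = (int)gz;
  if (i0 > V.nx - 2) i0 = V.nx > 1 ? V.nx - 2 : 0;
  if (j0 > V.ny - 2) j0 = V.ny > 1 ? V.ny - 2 : 0;
  if (k0 > V.nz - 2) k0 = V.nz > 1 ? V.nz - 2 : 0;
  double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  int i1 = V.nx > 1 ? i0 + 1 : i0;
  int j1 = V.ny > 1 ? j0 + 1 : j0;
  int k1 = V.nz > 1 ? k0 + 1 : k0;
  double c000 = V.at(i0, j0, k0), c100 = V.at(i1, j0, k0);
  double c010 = V.at(i0, j1, k0), c110 = V.at(i1, j1, k0);
  double c001 = V.at(i0, j0, k1), c101 = V.at(i1, j0, k1);
  double c011 = V.at(i0, j1, k1), c111 = V.at(i1, j1, k1);
  // d/dx
  gout[0] = cx ? 0.0 :
    ((c100 - c000) * (1 - fy) * (1 - fz) + (c110 - c010) * fy * (1 - fz) +
     (c101 - c001) * (1 - fy) * fz       + (c111 - c011) * fy * fz) / V.sx;
  // d/dy
  gout[1] = cy ? 0.0 :
    ((c010 - c000) * (1 - fx) * (1 - fz) + (c110 - c100) * fx * (1 - fz) +
     (c011 - c001) * (1 - fx) * fz       + (c111 - c101) * fx * fz) / V.sy;
  // d/dz
  gout[2] = cz ? 0.0 :
    ((c001 - c000) * (1 - fx) * (1 - fy) + (c101 - c100) * fx * (1 - fy) +
     (c011 - c010) * (1 - fx) * fy       + (c111 - c110) * fx * fy) / V.sz;
}

// Cone-beam source / detector frame for one gantry angle.
// Patient axes: x = left-right, y = anterior-posterior, z = superior-inferior.
// Angle 0 puts the source on the anterior (+y) side; rotation is
// counter-clockwise viewed from superior (+z).
struct CBFrame {
  double sx, sy, sz;    // source position
  double dx, dy, dz;    // unit source->isocenter axis
  double ux, uy, uz;    // detector lateral unit vector
  double vx, vy, vz;    // detector SI unit vector
  double sad, sdd;
};

inline CBFrame cb_frame(double sad, double sdd, double angle_deg) {
  double th = angle_deg * M_PI / 180.0;
  double st = std::sin(th), ct = std::cos(th);
  CBFrame F;
  F.sx = -sad * st; F.sy = sad * ct; F.sz = 0.0;
  F.dx = st;  F.dy = -ct; F.dz = 0.0;
  F.ux = ct;  F.uy = st;  F.uz = 0.0;
  F.vx = 0.0; F.vy = 0.0; F.vz = 1.0;
  F.sad = sad; F.sdd = sdd;
  return F;
}

// Intersection of the ray p(t) = S + t*w with the axis-aligned box spanned
// by the voxel-centre hull. Returns false when there is no intersection.
inline bool ray_box(const VolView& V,
                    double sx, double sy, double sz,
                    double wx, double wy, double wz,
                    double tmax, double* t0, double* t1) {
  double lo = 0.0, hi = tmax;
  const double o[3] = { V.ox, V.oy, V.oz };
  const double e[3] = { V.ox + (V.nx - 1) * V.sx,
                        V.oy + (V.ny - 1) * V.sy,
                        V.oz + (V.nz - 1) * V.sz };
  const double s[3] = { sx, sy, sz };
  const double w[3] = { wx, wy, wz };
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(w[a]) < 1e-12) {
      if (s[a] < o[a] || s[a] > e[a]) return false;
    } else {
      double ta = (o[a] - s[a]) / w[a];
      double tb = (e[a] - s[a]) / w[a];
      if (ta > tb) { double tmp = ta; ta = tb; tb = tmp; }
      if (ta > lo) lo = ta;
      if (tb < hi) hi = tb;
      if (lo >= hi) return false;
    }
  }
  *t0 = lo; *t1 = hi;
  return true;
}
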