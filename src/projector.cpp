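#include <Rcpp.h>
#include "interp.h"
using namespace Rcpp;

// Ray-driven cone-beam projector with trilinear sampling at a fixed step.
// The adjoint scatters the same weights, so <Pv,q> == <v,P'q> to rounding.

static inline void pixel_ray(const CBFrame& F, double pitch,
                             int nr, int nc, int r, int c,
                             double* wx, double* wy, double* wz, double* L) {
  double v = (r - (nr - 1) / 2.0) * pitch;
  double u = (c - (nc - 1) / 2.0) * pitch;
  double px = F.sx + F.sdd * F.dx + u * F.ux + v * F.vx;
  double py = F.sy + F.sdd * F.dy + u * F.uy + v * F.vy;
  double pz = F.sz + F.sdd * F.dz + u * F.uz + v * F.vz;
  double rx = px - F.sx, ry = py - F.sy, rz = pz - F.sz;
  double len = std::sqrt(rx * rx + ry * ry + rz * rz);
  *wx = rx / len; *wy = ry / len; *wz = rz / len;
  *L = len;
}

// [[Rcpp::export]]
NumericMatrix forward_project_cpp(NumericVector vol, IntegerVector dim,
                                  NumericVector spacing, NumericVector origin,
                                  double sad, double sdd, double pitch,
                                  int nr, int nc, double angle_deg,
                                  double step) {
  VolView V = { REAL(vol), dim[0], dim[1], dim[2],
                spacing[0], spacing[1], spacing[2],
                origin[0], origin[1], origin[2] };
  CBFrame F = cb_frame(sad, sdd, angle_deg);
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double wx, wy, wz, L;
      pixel_ray(F, pitch, nr, nc, r, c, &wx, &wy, &wz, &L);
      double t0, t1;
      if (!ray_box(V, F.sx, F.sy, F.sz, wx, wy, wz, 1e12, &t0, &t1)) continue;
      double len = t1 - t0;
      int nstep = (int)(len / step);
      double acc = 0.0;
      for (int k = 0; k < nstep; ++k) {
        double t = t0 + (k + 0.5) * step;
        acc += step * tri_sample_clamped(V, F.sx + t * wx, F.sy + t * wy,
                                         F.sz + t * wz);
      }
      double rem = len - nstep * step;
      if (rem > 1e-9) {
        double t = t0 + nstep * step + 0.5 * rem;
        acc += rem * tri_sample_clamped(V, F.sx + t * wx, F.sy + t * wy,
                                        F.sz + t * wz);
      }
      out(r, c) = acc;
    }
  }
  return out;
}

static inline void tri_scatter(double* vol, const VolView& V,
                               double x, double y, double z, double w) {
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
  std::size_t nx = V.nx, ny = V.ny;
#define IDX(i, j, k) ((std::size_t)(i) + nx * ((std::size_t)(j) + ny * (k)))
  vol[IDX(i0, j0, k0)] += w * (1 - fx) * (1 - fy) * (1 - fz);
  vol[IDX(i1, j0, k0)] += w * fx * (1 - fy) * (1 - fz);
  vol[IDX(i0, j1, k0)] += w * (1 - fx) * fy * (1 - fz);
  vol[IDX(i1, j1, k0)] += w * fx * fy * (1 - fz);
  vol[IDX(i0, j0, k1)] += w * (1 - fx) * (1 - fy) * fz;
  vol[IDX(i1, j0, k1)] += w * fx * (1 - fy) * fz;
  vol[IDX(i0, j1, k1)] += w * (1 - fx) * fy * fz;
  vol[IDX(i1, j1, k1)] += w * fx * fy * fz;
#undef IDX
}

// [[Rcpp::export]]
NumericVector back_project_cpp(NumericMatrix proj, IntegerVector dim,
                               NumericVector spacing, NumericVector origin,
                               double sad, double sdd, double pitch,
                               double angle_deg, double step) {
  int nr = proj.nrow(), nc = proj.ncol();
  NumericVector out((R_xlen_t)dim[0] * dim[1] * dim[2]);
  VolView V = { REAL(out), dim[0], dim[1], dim[2],
                spacing[0], spacing[1], spacing[2],
                origin[0], origin[1], origin[2] };
  CBFrame F = cb_frame(sad, sdd, angle_deg);
  double* vptr = REAL(out);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double q = proj(r, c);
      if (q == 0.0) continue;
      double wx, wy, wz, L;
      pixel_ray(F, pitch, nr, nc, r, c, &wx, &wy, &wz, &L);
      double t0, t1;
      if (!ray_box(V, F.sx, F.sy, F.sz, wx, wy, wz, 1e12, &t0, &t1)) continue;
      double len = t1 - t0;
      int nstep = (int)(len / step);
      for (int k = 0; k < nstep; ++k) {
        double t = t0 + (k + 0.5) * step;
        tri_scatter(vptr, V, F.sx + t * wx, F.sy + t * wy, F.sz + t * wz,
                    q * step);
      }
      double rem = len - nstep * step;
      if (rem > 1e-9) {
        double t = t0 + nstep * step + 0.5 * rem;
        tri_scatter(vptr, V, F.sx + t * wx, F.sy + t * wy, F.sz + t * wz,
                    q * rem);
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// ROI-restricted forward projection: identical ray discretisation, but
// only pixels inside the mask are computed (the optimisation's data term
// never reads the others).
// [[Rcpp::export]]
NumericMatrix forward_project_roi_cpp(NumericVector vol, IntegerVector dim,
                                      NumericVector spacing,
                                      NumericVector origin,
                                      double sad, double sdd, double pitch,
                                      int nr, int nc, double angle_deg,
                                      double step, LogicalMatrix roi) {
  VolView V = { REAL(vol), dim[0], dim[1], dim[2],
                spacing[0], spacing[1], spacing[2],
                origin[0], origin[1], origin[2] };
  CBFrame F = cb_frame(sad, sdd, angle_deg);
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!roi(r, c)) continue;
      double wx, wy, wz, L;
      pixel_ray(F, pitch, nr, nc, r, c, &wx, &wy, &wz, &L);
      double t0, t1;
      if (!ray_box(V, F.sx, F.sy, F.sz, wx, wy, wz, 1e12, &t0, &t1)) continue;
      double len = t1 - t0;
      int nstep = (int)(len / step);
      double acc = 0.0;
      for (int k = 0; k < nstep; ++k) {
        double t = t0 + (k + 0.5) * step;
        acc += step * tri_sample_clamped(V, F.sx + t * wx, F.sy + t * wy,
                                         F.sz + t * wz);
      }
      double rem = len - nstep * step;
      if (rem > 1e-9) {
        double t = t0 + nstep * step + 0.5 * rem;
        acc += rem * tri_sample_clamped(V, F.sx + t * wx, F.sy + t * wy,
                                        F.sz + t * wz);
      }
      out(r, c) = acc;
    }
  }
  return out;
}
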