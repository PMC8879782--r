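#include <Rcpp.h>
#include "interp.h"
using namespace Rcpp;

// Voxel-driven weighted backprojection for FDK. Projections are already
// cosine-weighted, Parker-weighted and ramp-filtered; this kernel applies
// the per-view angular weight dbeta and the 1/U^2 distance factor, where
// U = (distance from source along the central axis) / SAD.
// [[Rcpp::export]]
NumericVector fdk_backproject_cpp(NumericVector projs, IntegerVector pdim,
                                  NumericVector angles_deg,
                                  NumericVector dbeta,
                                  double sad, double sdd, double pitch,
                                  IntegerVector dim, NumericVector spacing,
                                  NumericVector origin) {
  int nr = pdim[0], nc = pdim[1], np = pdim[2];
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox);
  double* o = REAL(out);
  const double* P = REAL(projs);
  double mag = sdd / sad;
  double inv_pitch_iso = mag / pitch;   // isocenter mm -> detector pixels
  for (int p = 0; p < np; ++p) {
    CBFrame F = cb_frame(sad, sdd, angles_deg[p]);
    const double* pp = P + (std::size_t)p * nr * nc;
    double w_view = dbeta[p];
    R_xlen_t l = 0;
    for (int k = 0; k < nz; ++k) {
      double pz = origin[2] + k * spacing[2];
      for (int j = 0; j < ny; ++j) {
        double py = origin[1] + j * spacing[1];
        for (int i = 0; i < nx; ++i, ++l) {
          double px = origin[0] + i * spacing[0];
          double rx = px - F.sx, ry = py - F.sy, rz = pz - F.sz;
          double ell = rx * F.dx + ry * F.dy + rz * F.dz;
          if (ell < 1e-6) continue;
          double U = ell / sad;
          // detector coordinates scaled to the isocenter plane
          double uiso = (rx * F.ux + ry * F.uy + rz * F.uz) / U;
          double viso = (rx * F.vx + ry * F.vy + rz * F.vz) / U;
          double cc = uiso * inv_pitch_iso + (nc - 1) / 2.0;
          double rr = viso * inv_pitch_iso + (nr - 1) / 2.0;
          if (cc < 0 || cc > nc - 1 || rr < 0 || rr > nr - 1) continue;
          int c0 = (int)cc, r0 = (int)rr;
          if (c0 > nc - 2) c0 = nc - 2;
          if (r0 > nr - 2) r0 = nr - 2;
          double fc = cc - c0, fr = rr - r0;
          double val =
            pp[r0 + nr * c0] * (1 - fr) * (1 - fc) +
            pp[r0 + 1 + nr * c0] * fr * (1 - fc) +
            pp[r0 + nr * (c0 + 1)] * (1 - fr) * fc +
            pp[r0 + 1 + nr * (c0 + 1)] * fr * fc;
          o[l] += w_view * val / (U * U);
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
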