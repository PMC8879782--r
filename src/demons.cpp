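#include <Rcpp.h>
#include "interp.h"
#include <vector>
using namespace Rcpp;

// Separable Gaussian smoothing of one scalar component, sigma in voxels per
// axis; boundary handled by kernel renormalisation (no implicit zero inflow).
static void gauss_smooth_inplace(double* v, int nx, int ny, int nz,
                                 const double sigma_vox[3]) {
  const int n[3] = { nx, ny, nz };
  const std::size_t stride[3] = { 1, (std::size_t)nx, (std::size_t)nx * ny };
  std::size_t nvox = (std::size_t)nx * ny * nz;
  std::vector<double> tmp(nvox);
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s < 1e-3) continue;
    int rad = (int)std::ceil(2.5 * s);
    std::vector<double> ker(2 * rad + 1);
    for (int t = -rad; t <= rad; ++t)
      ker[t + rad] = std::exp(-0.5 * (t / s) * (t / s));
    // iterate over all lines along axis ax
    int na = n[ax];
    std::size_t sa = stride[ax];
    int nb = n[(ax + 1) % 3], nc2 = n[(ax + 2) % 3];
    std::size_t sb = stride[(ax + 1) % 3], sc = stride[(ax + 2) % 3];
    for (int c = 0; c < nc2; ++c)
      for (int b = 0; b < nb; ++b) {
        std::size_t base = (std::size_t)b * sb + (std::size_t)c * sc;
        for (int a = 0; a < na; ++a) {
          double acc = 0.0, wsum = 0.0;
          int lo = a - rad < 0 ? -a : -rad;
          int hi = a + rad > na - 1 ? na - 1 - a : rad;
          for (int t = lo; t <= hi; ++t) {
            double w = ker[t + rad];
            acc += w * v[base + (std::size_t)(a + t) * sa];
            wsum += w;
          }
          tmp[base + (std::size_t)a * sa] = acc / wsum;
        }
      }
    for (std::size_t l = 0; l < nvox; ++l) v[l] = tmp[l];
  }
}

// [[Rcpp::export]]
NumericVector gauss_smooth_cpp(NumericVector vol, IntegerVector dim,
                               NumericVector sigma_vox) {
  NumericVector out = clone(vol);
  double s[3] = { sigma_vox[0], sigma_vox[1], sigma_vox[2] };
  gauss_smooth_inplace(REAL(out), dim[0], dim[1], dim[2], s);
  out.attr("dim") = vol.attr("dim");
  return out;
}

// Thirion demons at a single resolution level. fixed/moving share the grid;
// field is the (possibly non-zero) initial displacement, nvox x 3 in mm.
// Returns the refined field plus convergence diagnostics.
// [[Rcpp::export]]
List demons_level_cpp(NumericVector fixed, NumericVector moving,
                      IntegerVector dim, NumericVector spacing,
                      NumericVector origin, NumericVector field,
                      int max_iter, double sigma_update_mm,
                      double sigma_total_mm, double diff_thresh,
                      double tol_mm) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  VolView Vm = { REAL(moving), nx, ny, nz,
                 spacing[0], spacing[1], spacing[2],
                 origin[0], origin[1], origin[2] };
  const double* F = REAL(fixed);
  NumericVector fld = clone(field);
  double* D = REAL(fld);

  // central-difference gradient of a raster (one-sided at edges), 1/mm
  auto grad_of = [&](const double* img, std::vector<double>& ox,
                     std::vector<double>& oy, std::vector<double>& oz) {
    R_xlen_t l = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++l) {
          int ip = i < nx - 1 ? i + 1 : i, im = i > 0 ? i - 1 : i;
          int jp = j < ny - 1 ? j + 1 : j, jm = j > 0 ? j - 1 : j;
          int kp = k < nz - 1 ? k + 1 : k, km = k > 0 ? k - 1 : k;
#define AT(a, b, c) img[(std::size_t)(a) + (std::size_t)nx * ((std::size_t)(b) + (std::size_t)ny * (c))]
          ox[l] = (AT(ip, j, k) - AT(im, j, k)) / ((ip - im) * spacing[0]);
          oy[l] = (AT(i, jp, k) - AT(i, jm, k)) / ((jp - jm) * spacing[1]);
          oz[l] = (AT(i, j, kp) - AT(i, j, km)) / ((kp - km) * spacing[2]);
#undef AT
        }
  };
  // fixed-image gradient, computed once; per-iteration the warped moving
  // image's gradient is averaged in (symmetric / ESM-style force), which
  // damps the per-voxel oscillation of the one-sided Thirion force
  std::vector<double> gfx(nvox), gfy(nvox), gfz(nvox);
  grad_of(F, gfx, gfy, gfz);
  std::vector<double> W(nvox), gwx(nvox), gwy(nvox), gwz(nvox);

  double kappa = (spacing[0] + spacing[1] + spacing[2]) / 3.0;
  double kappa2 = kappa * kappa;
  double su[3] = { sigma_update_mm / spacing[0], sigma_update_mm / spacing[1],
                   sigma_update_mm / spacing[2] };
  double st[3] = { sigma_total_mm / spacing[0], sigma_total_mm / spacing[1],
                   sigma_total_mm / spacing[2] };

  std::vector<double> ux(nvox), uy(nvox), uz(nvox);
  int iter = 0;
  double mean_update = R_PosInf, final_resid = NA_REAL;
  NumericVector resid_hist(max_iter);

  for (iter = 0; iter < max_iter; ++iter) {
    double resid = 0.0;
    R_xlen_t l = 0;
    for (int k = 0; k < nz; ++k) {
      double pz = origin[2] + k * spacing[2];
      for (int j = 0; j < ny; ++j) {
        double py = origin[1] + j * spacing[1];
        for (int i = 0; i < nx; ++i, ++l) {
          double px = origin[0] + i * spacing[0];
          W[l] = tri_sample_clamped(Vm, px + D[l], py + D[l + nvox],
                                    pz + D[l + 2 * nvox]);
        }
      }
    }
    grad_of(W.data(), gwx, gwy, gwz);
    for (l = 0; l < nvox; ++l) {
      double diff = F[l] - W[l];
      resid += diff * diff;
      double gx = 0.5 * (gfx[l] + gwx[l]);
      double gy = 0.5 * (gfy[l] + gwy[l]);
      double gz = 0.5 * (gfz[l] + gwz[l]);
      double den = gx * gx + gy * gy + gz * gz + (diff * diff) / kappa2;
      if (std::fabs(diff) < diff_thresh || den < 1e-12) {
        ux[l] = uy[l] = uz[l] = 0.0;
      } else {
        double f = diff / den;
        ux[l] = f * gx;
        uy[l] = f * gy;
        uz[l] = f * gz;
      }
    }
    resid_hist[iter] = std::sqrt(resid / nvox);
    gauss_smooth_inplace(ux.data(), nx, ny, nz, su);
    gauss_smooth_inplace(uy.data(), nx, ny, nz, su);
    gauss_smooth_inplace(uz.data(), nx, ny, nz, su);
    double upsum = 0.0;
    for (R_xlen_t m = 0; m < nvox; ++m) {
      D[m] += ux[m];
      D[m + nvox] += uy[m];
      D[m + 2 * nvox] += uz[m];
      upsum += std::sqrt(ux[m] * ux[m] + uy[m] * uy[m] + uz[m] * uz[m]);
    }
    gauss_smooth_inplace(D, nx, ny, nz, st);
    gauss_smooth_inplace(D + nvox, nx, ny, nz, st);
    gauss_smooth_inplace(D + 2 * nvox, nx, ny, nz, st);
    mean_update = upsum / nvox;
    if (mean_update < tol_mm) { ++iter; break; }
  }
  final_resid = resid_hist[iter - 1 < 0 ? 0 : iter - 1];
  return List::create(_["field"] = fld, _["iterations"] = iter,
                      _["mean_update_mm"] = mean_update,
                      _["rms_residual"] = final_resid,
                      _["residual_history"] = resid_hist[Range(0, iter - 1)]);
}
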