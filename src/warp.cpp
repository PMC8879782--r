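#include <Rcpp.h>
#include "interp.h"
using namespace Rcpp;

// Pull-back warp: out(p) = vol(p + D(p)), world mm, trilinear, clamped.
// [[Rcpp::export]]
NumericVector warp_volume_cpp(NumericVector vol, IntegerVector dim,
                              NumericVector spacing, NumericVector origin,
                              NumericVector dvf) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  VolView V = { REAL(vol), nx, ny, nz,
                spacing[0], spacing[1], spacing[2],
                origin[0], origin[1], origin[2] };
  const double* D = REAL(dvf);
  NumericVector out(nvox);
  double* o = REAL(out);
  R_xlen_t l = 0;
  for (int k = 0; k < nz; ++k) {
    double pz = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; ++j) {
      double py = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i, ++l) {
        double px = origin[0] + i * spacing[0];
        o[l] = tri_sample_clamped(V, px + D[l], py + D[l + nvox],
                                  pz + D[l + 2 * nvox]);
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Trilinear values of a volume at arbitrary world points (m x 3), clamped.
// [[Rcpp::export]]
NumericVector sample_volume_cpp(NumericVector vol, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix pts) {
  VolView V = { REAL(vol), dim[0], dim[1], dim[2],
                spacing[0], spacing[1], spacing[2],
                origin[0], origin[1], origin[2] };
  int m = pts.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = tri_sample_clamped(V, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// Resample a volume onto a new grid (world-coordinate trilinear, clamped).
// [[Rcpp::export]]
NumericVector resample_volume_cpp(NumericVector vol, IntegerVector dim,
                                  NumericVector spacing, NumericVector origin,
                                  IntegerVector odim, NumericVector ospacing,
                                  NumericVector oorigin) {
  VolView V = { REAL(vol), dim[0], dim[1], dim[2],
                spacing[0], spacing[1], spacing[2],
                origin[0], origin[1], origin[2] };
  int nx = odim[0], ny = odim[1], nz = odim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* o = REAL(out);
  R_xlen_t l = 0;
  for (int k = 0; k < nz; ++k) {
    double pz = oorigin[2] + k * ospacing[2];
    for (int j = 0; j < ny; ++j) {
      double py = oorigin[1] + j * ospacing[1];
      for (int i = 0; i < nx; ++i, ++l)
        o[l] = tri_sample_clamped(V, oorigin[0] + i * ospacing[0], py, pz);
    }
  }
  out.attr("dim") = odim;
  return out;
}

// Block-mean downsampling by an integer factor per axis (registration pyramid).
// [[Rcpp::export]]
NumericVector block_downsample_cpp(NumericVector vol, IntegerVector dim,
                                   int factor) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int mx = nx / factor, my = ny / factor, mz = nz / factor;
  NumericVector out((R_xlen_t)mx * my * mz);
  const double* v = REAL(vol);
  double* o = REAL(out);
  double inv = 1.0 / ((double)factor * factor * factor);
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        double acc = 0.0;
        for (int dk = 0; dk < factor; ++dk)
          for (int dj = 0; dj < factor; ++dj)
            for (int di = 0; di < factor; ++di)
              acc += v[(std::size_t)(i * factor + di) +
                       (std::size_t)nx * ((std::size_t)(j * factor + dj) +
                                          (std::size_t)ny * (k * factor + dk))];
        o[(std::size_t)i + (std::size_t)mx * ((std::size_t)j + (std::size_t)my * k)] =
          acc * inv;
      }
  out.attr("dim") = IntegerVector::create(mx, my, mz);
  return out;
}

// Chain-rule contraction for the coefficient gradient:
//   g_i = sum_p B(p) * < grad f0 (p + D(p)), v_i(p) >
// B is a volume-shaped sensitivity (the back-projected masked residual),
// grad f0 is the exact derivative of the trilinear interpolant, and modes
// holds the eigenvector fields as columns of a (3*nvox) x N matrix.
// [[Rcpp::export]]
NumericVector grad_contract_cpp(NumericVector f0, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                NumericVector dvf, NumericVector bvol,
                                NumericMatrix modes) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  int nmodes = modes.ncol();
  VolView V = { REAL(f0), nx, ny, nz,
                spacing[0], spacing[1], spacing[2],
                origin[0], origin[1], origin[2] };
  const double* D = REAL(dvf);
  const double* B = REAL(bvol);
  NumericVector g(nmodes);
  double grad[3];
  R_xlen_t l = 0;
  for (int k = 0; k < nz; ++k) {
    double pz = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; ++j) {
      double py = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i, ++l) {
        double b = B[l];
        if (b == 0.0) continue;
        double px = origin[0] + i * spacing[0];
        tri_grad_clamped(V, px + D[l], py + D[l + nvox], pz + D[l + 2 * nvox],
                         grad);
        for (int m = 0; m < nmodes; ++m) {
          g[m] += b * (grad[0] * modes(l, m) +
                       grad[1] * modes(l + nvox, m) +
                       grad[2] * modes(l + 2 * nvox, m));
        }
      }
    }
  }
  return g;
}

// Fused model-warp: out(p) = f0(p + Dbar(p) + sum_m u_m v_m(p)) without
// materialising the displacement field.
// [[Rcpp::export]]
NumericVector warp_model_cpp(NumericVector f0, IntegerVector dim,
                             NumericVector spacing, NumericVector origin,
                             NumericVector mean_dvf, NumericMatrix modes,
                             NumericVector u) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  int nm = u.size();
  VolView V = { REAL(f0), nx, ny, nz,
                spacing[0], spacing[1], spacing[2],
                origin[0], origin[1], origin[2] };
  const double* M = REAL(mean_dvf);
  NumericVector out(nvox);
  double* o = REAL(out);
  R_xlen_t l = 0;
  for (int k = 0; k < nz; ++k) {
    double pz = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; ++j) {
      double py = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i, ++l) {
        double px = origin[0] + i * spacing[0];
        double dx = M[l], dy = M[l + nvox], dz = M[l + 2 * nvox];
        for (int m = 0; m < nm; ++m) {
          double um = u[m];
          dx += um * modes(l, m);
          dy += um * modes(l + nvox, m);
          dz += um * modes(l + 2 * nvox, m);
        }
        o[l] = tri_sample_clamped(V, px + dx, py + dy, pz + dz);
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Fused coefficient gradient, evaluating the model field on the fly:
//   g_m = sum_p B(p) * < grad f0 (p + D_u(p)), v_m(p) >
// [[Rcpp::export]]
NumericVector grad_contract_model_cpp(NumericVector f0, IntegerVector dim,
                                      NumericVector spacing,
                                      NumericVector origin,
                                      NumericVector mean_dvf,
                                      NumericMatrix modes, NumericVector u,
                                      NumericVector bvol) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  int nm = u.size();
  VolView V = { REAL(f0), nx, ny, nz,
                spacing[0], spacing[1], spacing[2],
                origin[0], origin[1], origin[2] };
  const double* M = REAL(mean_dvf);
  const double* B = REAL(bvol);
  NumericVector g(nm);
  double grad[3];
  R_xlen_t l = 0;
  for (int k = 0; k < nz; ++k) {
    double pz = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; ++j) {
      double py = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i, ++l) {
        double b = B[l];
        if (b == 0.0) continue;
        double px = origin[0] + i * spacing[0];
        double dx = M[l], dy = M[l + nvox], dz = M[l + 2 * nvox];
        for (int m = 0; m < nm; ++m) {
          double um = u[m];
          dx += um * modes(l, m);
          dy += um * modes(l + nvox, m);
          dz += um * modes(l + 2 * nvox, m);
        }
        tri_grad_clamped(V, px + dx, py + dy, pz + dz, grad);
        for (int m = 0; m < nm; ++m) {
          g[m] += b * (grad[0] * modes(l, m) +
                       grad[1] * modes(l + nvox, m) +
                       grad[2] * modes(l + 2 * nvox, m));
        }
      }
    }
  }
  return g;
}
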