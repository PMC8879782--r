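#' Cone-beam forward projection
#'
#' Computes the line integral of attenuation along the ray from the source
#' through each detector pixel centre (the linear operator P). Rays are
#' sampled at a fixed step with trilinear interpolation; samples outside the
#' voxel-centre hull contribute zero. For fixed geometry the operator is
#' linear in the volume, and [back_project()] is its exact adjoint (the two
#' share one ray discretisation).
#'
#' @param volume a [volume3d()].
#' @param geom a [cone_beam_geometry()]; `angle_deg` selects the view.
#' @param step_mm ray sampling step; defaults to half the smallest voxel
#'   spacing.
#' @return a [projection2d()].
#' @export
forward_project <- function(volume, geom, step_mm = NULL) {
  stopifnot(inherits(volume, "volume3d"), inherits(geom, "cone_beam_geometry"))
  if (is.null(step_mm)) step_mm <- min(volume$spacing) / 2
  px <- forward_project_cpp(as.vector(volume$voxels), dim(volume$voxels),
                            volume$spacing, volume$origin,
                            geom$sad_mm, geom$sdd_mm, geom$pixel_mm,
                            geom$detector_rows, geom$detector_cols,
                            geom$angle_deg, step_mm)
  if (all(px == 0) && any(volume$voxels != 0))
    warning("volume is entirely outside the projector field of view; projection is all zero")
  projection2d(px, geom)
}

#' Adjoint of the cone-beam forward projection
#'
#' Applies the transpose of the ray-driven projector: each detector value is
#' scattered back along its ray with the same sampling weights used by
#' [forward_project()], so the pair satisfies the adjoint identity
#' `<P v, q> == <v, P' q>` under the standard (unweighted) inner products.
#' This is artifact plumbing for the optimisation gradient; it is not a
#' tomographic reconstruction (see [fdk_reconstruct()] for that).
#'
#' @param proj a [projection2d()].
#' @param grid a [volume3d()] template defining the output grid (shape,
#'   spacing, origin); its voxel values are ignored.
#' @param step_mm ray sampling step; must match the forward call to realise
#'   the exact adjoint. Defaults to half the smallest grid spacing.
#' @return a [volume3d()] holding `P' q`.
#' @export
back_project <- function(proj, grid, step_mm = NULL) {
  stopifnot(inherits(proj, "projection2d"), inherits(grid, "volume3d"))
  geom <- proj$geometry
  if (nrow(proj$pixels) != geom$detector_rows ||
      ncol(proj$pixels) != geom$detector_cols)
    stop("projection dimensions do not match detector geometry")
  if (is.null(step_mm)) step_mm <- min(grid$spacing) / 2
  v <- back_project_cpp(proj$pixels, dim(grid$voxels), grid$spacing,
                        grid$origin, geom$sad_mm, geom$sdd_mm, geom$pixel_mm,
                        geom$angle_deg, step_mm)
  volume3d(v, grid$spacing, grid$origin)
}
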