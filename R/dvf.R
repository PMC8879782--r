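#' Displacement vector field (DVF)
#'
#' A per-voxel 3-component displacement in world mm, defined on a reference
#' grid. Fields are stored in the pull-back (reference-sampling) convention
#' used by [warp_volume()]: a volume deformed by the field samples the input
#' at `p + D(p)`.
#'
#' @param field 4D numeric array `(nx, ny, nz, 3)`, components ordered
#'   (LR, AP, SI) in mm.
#' @param spacing_mm,origin_mm grid description, as in [volume3d()].
#' @param provenance optional free-form note (e.g. fixed/moving volume IDs).
#' @export
dvf <- function(field, spacing_mm, origin_mm = NULL, provenance = NULL) {
  d <- dim(field)
  if (length(d) != 4L || d[4] != 3L)
    stop("field must be a (nx, ny, nz, 3) array")
  if (!all(is.finite(field))) stop("DVF contains non-finite values")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stop("spacing must be > 0")
  if (is.null(origin_mm)) origin_mm <- -(d[1:3] - 1) / 2 * spacing_mm
  structure(list(field = field, spacing = spacing_mm,
                 origin = rep_len(as.numeric(origin_mm), 3L),
                 provenance = provenance),
            class = "dvf")
}

#' @export
print.dvf <- function(x, ...) {
  d <- dim(x$field)
  mx <- sqrt(max(x$field[, , , 1]^2 + x$field[, , , 2]^2 + x$field[, , , 3]^2))
  cat(sprintf("dvf: %d x %d x %d @ (%g, %g, %g) mm, max |D| = %.3f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], mx))
  if (!is.null(x$provenance)) cat(" provenance:", x$provenance, "\n")
  invisible(x)
}

zero_dvf <- function(grid) {
  d <- dim(grid$voxels)
  dvf(array(0, c(d, 3L)), grid$spacing, grid$origin, provenance = "zero field")
}

# grids must agree between a volume and a DVF (or two grid-carrying objects)
check_same_grid <- function(a, b) {
  da <- if (!is.null(a$voxels)) dim(a$voxels) else dim(a$field)[1:3]
  db <- if (!is.null(b$voxels)) dim(b$voxels) else dim(b$field)[1:3]
  if (!identical(da, db) ||
      max(abs(a$spacing - b$spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-6)
    stop("grid mismatch: shapes/spacing/origin differ")
  invisible(TRUE)
}

#' Deform a volume with a displacement field
#'
#' Pull-back (backward) warping with trilinear interpolation:
#' `out(p) = vol(p + D(p))` in world mm. Out-of-bounds samples take the
#' boundary-clamped value. A zero field reproduces the input exactly.
#'
#' @param vol a [volume3d()].
#' @param dvf a [dvf()] on the same grid.
#' @return the deformed [volume3d()].
#' @export
warp_volume <- function(vol, dvf) {
  stopifnot(inherits(vol, "volume3d"), inherits(dvf, "dvf"))
  check_same_grid(vol, dvf)
  out <- warp_volume_cpp(as.vector(vol$voxels), dim(vol$voxels),
                         vol$spacing, vol$origin, as.vector(dvf$field))
  volume3d(out, vol$spacing, vol$origin)
}

# trilinear sample of a DVF at world points; returns m x 3 matrix (mm)
sample_dvf <- function(dvf, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  d <- dim(dvf$field)[1:3]
  out <- matrix(0, nrow(pts), 3)
  for (a in 1:3)
    out[, a] <- sample_volume_cpp(as.vector(dvf$field[, , , a]), d,
                                  dvf$spacing, dvf$origin, pts)
  out
}
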