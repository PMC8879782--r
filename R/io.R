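#' Read and write volumes and displacement fields as NIfTI
#'
#' Volumes are stored as 3D NIfTI (`.nii`/`.nii.gz`) with the voxel spacing
#' in `pixdim` and the world origin in the sform affine; displacement
#' fields are stored as 4D NIfTI with the three displacement components
#' (mm) along the fourth dimension.
#'
#' @param vol a [volume3d()].
#' @param path output file path.
#' @return `write_*` return the path invisibly; `read_*` return the
#'   reconstructed object.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  write_nifti_grid(vol$voxels, vol$spacing, vol$origin, path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  g <- read_nifti_grid(path)
  if (length(dim(g$data)) != 3L) stop("expected a 3D NIfTI volume")
  volume3d(g$data, g$spacing, g$origin)
}

#' @rdname write_volume
#' @param field a [dvf()].
#' @export
write_dvf <- function(field, path) {
  stopifnot(inherits(field, "dvf"))
  write_nifti_grid(field$field, field$spacing, field$origin, path)
}

#' @rdname write_volume
#' @export
read_dvf <- function(path) {
  g <- read_nifti_grid(path)
  if (length(dim(g$data)) != 4L || dim(g$data)[4] != 3L)
    stop("expected a 4D NIfTI displacement field with 3 components")
  dvf(g$data, g$spacing, g$origin)
}

write_nifti_grid <- function(data, spacing, origin, path) {
  img <- RNifti::asNifti(data)
  aff <- diag(4)
  aff[1, 1] <- spacing[1]; aff[2, 2] <- spacing[2]; aff[3, 3] <- spacing[3]
  aff[1:3, 4] <- origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_grid <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  sp <- abs(c(aff[1, 1], aff[2, 2], aff[3, 3]))
  org <- aff[1:3, 4]
  # RNifti reports xforms in RAS; our axes are stored unflipped, so undo a
  # sign flip if one was applied to the first axes
  if (aff[1, 1] < 0) org[1] <- org[1] + (dim(img)[1] - 1) * aff[1, 1]
  if (aff[2, 2] < 0) org[2] <- org[2] + (dim(img)[2] - 1) * aff[2, 2]
  list(data = as.array(img), spacing = sp, origin = org)
}
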