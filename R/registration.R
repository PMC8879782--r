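#' Demons registration parameters
#'
#' Multiresolution Thirion demons: at each pyramid level the intensity
#' force `(F - M(D)) grad F / (|grad F|^2 + (F - M(D))^2 / k^2)` (k = mean
#' voxel spacing) is Gaussian-smoothed and accumulated into the field,
#' which is itself smoothed every iteration (fluid-like plus diffusion-like
#' regularisation).
#'
#' @param shrink_factors integer pyramid shrink factor per level, coarse to
#'   fine (the last level is usually 1 = full resolution).
#' @param iterations iterations per level, same length as `shrink_factors`.
#' @param sigma_update_mm Gaussian sigma applied to each update field (mm).
#'   The default corresponds to about two voxels of the default grids;
#'   scale it with the voxel size of your data.
#' @param sigma_total_mm Gaussian sigma applied to the accumulated field
#'   (mm); about one voxel by default.
#' @param diff_threshold intensity differences below this are ignored.
#' @param tol_mm stop a level once the mean update magnitude drops below
#'   this (mm).
#' @return an object of class `demons_params`.
#' @export
demons_params <- function(shrink_factors = c(4, 2, 1),
                          iterations = c(50, 30, 20),
                          sigma_update_mm = 8, sigma_total_mm = 4,
                          diff_threshold = 0, tol_mm = 1e-3) {
  if (length(iterations) != length(shrink_factors))
    stop("iterations and shrink_factors must have equal length")
  if (any(iterations < 1)) stop("iterations must be >= 1")
  if (sigma_update_mm < 0 || sigma_total_mm < 0) stop("sigma must be >= 0")
  structure(list(shrink_factors = as.integer(shrink_factors),
                 iterations = as.integer(iterations),
                 sigma_update_mm = sigma_update_mm,
                 sigma_total_mm = sigma_total_mm,
                 diff_threshold = diff_threshold, tol_mm = tol_mm),
            class = "demons_params")
}

downsample_volume <- function(vol, f) {
  if (f == 1) return(vol)
  v <- block_downsample_cpp(as.vector(vol$voxels), dim(vol$voxels), f)
  volume3d(v, vol$spacing * f, vol$origin + (f - 1) / 2 * vol$spacing)
}

# resample a field component-wise onto a target grid (world-consistent)
resample_field <- function(field, spacing, origin, tdim, tspacing, torigin) {
  out <- array(0, c(tdim, 3L))
  for (a in 1:3)
    out[, , , a] <- resample_volume_cpp(as.vector(field[, , , a]),
                                        dim(field)[1:3], spacing, origin,
                                        tdim, tspacing, torigin)
  out
}

#' Demons deformable registration of two volumes
#'
#' Estimates a displacement field `D` such that
#' `warp_volume(moving, D) ~ fixed`, by coarse-to-fine Thirion demons with
#' Gaussian regularisation. Fully deterministic.
#'
#' @param fixed,moving [volume3d()] objects on the same grid.
#' @param params a [demons_params()].
#' @return a [dvf()] on the fixed grid; attribute `diagnostics` records
#'   per-level iterations and residuals.
#' @export
demons_register <- function(fixed, moving, params = demons_params()) {
  stopifnot(inherits(fixed, "volume3d"), inherits(moving, "volume3d"))
  check_same_grid(fixed, moving)
  if (!all(is.finite(fixed$voxels)) || !all(is.finite(moving$voxels)))
    stop("non-finite intensities in registration input")
  nlev <- length(params$shrink_factors)
  field <- NULL
  fs <- fixed$spacing; fo <- fixed$origin
  diag <- vector("list", nlev)
  for (l in seq_len(nlev)) {
    f <- params$shrink_factors[l]
    fx <- downsample_volume(fixed, f)
    mv <- downsample_volume(moving, f)
    d <- dim(fx$voxels)
    if (is.null(field)) {
      field <- array(0, c(d, 3L))
    } else {
      field <- resample_field(field, prev_spacing, prev_origin, d,
                              fx$spacing, fx$origin)
    }
    res <- demons_level_cpp(as.vector(fx$voxels), as.vector(mv$voxels), d,
                            fx$spacing, fx$origin, as.vector(field),
                            params$iterations[l], params$sigma_update_mm,
                            params$sigma_total_mm, params$diff_threshold,
                            params$tol_mm)
    field <- array(res$field, c(d, 3L))
    hist <- res$residual_history
    if (length(hist) > 3 && all(diff(utils::tail(hist, 4)) > 0))
      warning(sprintf("demons level %d: residual increasing persistently; returning best-so-far field", l))
    diag[[l]] <- list(shrink = f, iterations = res$iterations,
                      rms_residual = res$rms_residual,
                      mean_update_mm = res$mean_update_mm)
    prev_spacing <- fx$spacing; prev_origin <- fx$origin
  }
  out <- dvf(field, fs, fo, provenance = "demons_register(fixed, moving)")
  attr(out, "diagnostics") <- diag
  out
}

#' Register every 4D-CBCT phase to the reference phase
#'
#' For each phase volume, runs [demons_register()] with `fixed = phase`,
#' `moving = reference`, so every stored field deforms the reference volume
#' into that phase via pull-back warping (the convention required by the
#' motion model and the projection-matching optimisation). The reference's
#' own entry is the zero field.
#'
#' @param phases list of [volume3d()] on a common grid (>= 2).
#' @param reference_index 1-based index of the reference phase
#'   (conventionally peak-exhale).
#' @param params a [demons_params()].
#' @return list of [dvf()], one per phase.
#' @export
register_all_phases <- function(phases, reference_index,
                                params = demons_params()) {
  if (length(phases) < 2) stop("need at least 2 phases")
  ref <- phases[[reference_index]]
  lapply(seq_along(phases), function(i) {
    if (i == reference_index) {
      d <- zero_dvf(ref)
      d$provenance <- "reference phase (zero field)"
      return(d)
    }
    d <- demons_register(phases[[i]], ref, params)
    d$provenance <- sprintf("demons: reference -> phase %d (pull-back)", i)
    d
  })
}
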