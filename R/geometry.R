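#' Cone-beam acquisition geometry
#'
#' Describes a flat-panel cone-beam system: source-to-axis distance (SAD),
#' source-to-detector distance (SDD), detector raster and pixel pitch, the
#' current gantry angle and the sweep used for acquisition. Patient axes are
#' x = left-right, y = anterior-posterior, z = superior-inferior (SI).
#' Gantry angle 0 places the source on the anterior side; rotation is
#' counter-clockwise viewed from superior. Detector coordinates are in mm
#' with (0, 0) at the principal point; the detector v axis is parallel to
#' the patient SI axis.
#'
#' @param sad_mm source-to-axis distance (mm); must be positive.
#' @param sdd_mm source-to-detector distance (mm); must exceed `sad_mm`.
#' @param detector_rows,detector_cols detector raster size (pixels).
#' @param pixel_mm detector pixel pitch (mm, square pixels).
#' @param angle_deg current gantry angle (degrees).
#' @param arc_start_deg,arc_span_deg gantry sweep description (degrees).
#'
#' @return an object of class `cone_beam_geometry`.
#' @export
cone_beam_geometry <- function(sad_mm = 1000, sdd_mm = 1536,
                               detector_rows = 512, detector_cols = 512,
                               pixel_mm = 0.8, angle_deg = 0,
                               arc_start_deg = 0, arc_span_deg = 200) {
  if (!is.numeric(sad_mm) || sad_mm <= 0)
    stop("invalid geometry: sad_mm must be > 0")
  if (!is.numeric(sdd_mm) || sdd_mm <= sad_mm)
    stop("invalid geometry: sdd_mm must exceed sad_mm")
  if (detector_rows < 1 || detector_cols < 1)
    stop("invalid geometry: detector dimensions must be >= 1")
  if (pixel_mm <= 0) stop("invalid geometry: pixel_mm must be > 0")
  structure(list(sad_mm = sad_mm, sdd_mm = sdd_mm,
                 detector_rows = as.integer(detector_rows),
                 detector_cols = as.integer(detector_cols),
                 pixel_mm = pixel_mm, angle_deg = angle_deg,
                 arc_start_deg = arc_start_deg, arc_span_deg = arc_span_deg),
            class = "cone_beam_geometry")
}

#' @export
print.cone_beam_geometry <- function(x, ...) {
  cat(sprintf(
    "cone_beam_geometry: SAD %.1f mm, SDD %.1f mm (mag %.3f)\n  detector %d x %d px @ %.3f mm, angle %.2f deg, arc [%g, %g+%g] deg\n",
    x$sad_mm, x$sdd_mm, x$sdd_mm / x$sad_mm, x$detector_rows,
    x$detector_cols, x$pixel_mm, x$angle_deg, x$arc_start_deg,
    x$arc_start_deg, x$arc_span_deg))
  invisible(x)
}

set_angle <- function(geom, angle_deg) {
  geom$angle_deg <- angle_deg
  geom
}

#' 3D attenuation volume
#'
#' A 3D scalar raster of attenuation values (relative mm^-1) with voxel
#' spacing and world origin. The world coordinate of voxel `(i, j, k)`
#' (1-based R indices) is `origin + (c(i, j, k) - 1) * spacing`. By default
#' the origin centres the volume on the isocenter.
#'
#' @param voxels 3D numeric array, dimension order (x, y, z) = (LR, AP, SI).
#' @param spacing_mm voxel spacing per axis (mm), length 1 or 3.
#' @param origin_mm world coordinates of the centre of voxel (1,1,1); when
#'   `NULL` the volume is centred on the isocenter.
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(voxels, spacing_mm, origin_mm = NULL) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stop("spacing must be > 0 on all axes")
  if (!all(is.finite(voxels))) stop("volume contains non-finite values")
  if (is.null(origin_mm)) origin_mm <- -(dim(voxels) - 1) / 2 * spacing_mm
  origin_mm <- rep_len(as.numeric(origin_mm), 3L)
  structure(list(voxels = voxels, spacing = spacing_mm, origin = origin_mm),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("volume3d: %d x %d x %d voxels @ (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# world extent of the voxel-centre hull
volume_extent <- function(vol) {
  d <- dim(vol$voxels)
  rbind(lo = vol$origin, hi = vol$origin + (d - 1) * vol$spacing)
}

#' Single cone-beam projection
#'
#' @param pixels matrix of line integrals; rows run along the detector SI
#'   (v) axis, columns along the lateral (u) axis.
#' @param geometry the [cone_beam_geometry()] at which it was acquired.
#' @param frame_index 1-based frame number within an acquisition.
#' @param time_s acquisition time stamp (s).
#' @return an object of class `projection2d`.
#' @export
projection2d <- function(pixels, geometry, frame_index = 1L, time_s = 0) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (nrow(pixels) != geometry$detector_rows ||
      ncol(pixels) != geometry$detector_cols)
    stop("projection dimensions do not match detector geometry")
  if (!all(is.finite(pixels))) stop("projection contains non-finite values")
  structure(list(pixels = pixels, geometry = geometry,
                 frame_index = as.integer(frame_index), time_s = time_s),
            class = "projection2d")
}

#' Stack of cone-beam projections over a gantry sweep
#'
#' @param pixels 3D array (detector_rows x detector_cols x n_frames).
#' @param geometry base [cone_beam_geometry()] (angle varies per frame).
#' @param angles_deg,times_s per-frame gantry angle and time stamp.
#' @export
projection_stack <- function(pixels, geometry, angles_deg, times_s) {
  d <- dim(pixels)
  if (length(d) != 3L) stop("pixels must be a 3D array")
  if (d[1] != geometry$detector_rows || d[2] != geometry$detector_cols)
    stop("projection dimensions do not match detector geometry")
  if (length(angles_deg) != d[3] || length(times_s) != d[3])
    stop("angles/times length must match frame count")
  structure(list(pixels = pixels, geometry = geometry,
                 angles_deg = as.numeric(angles_deg),
                 times_s = as.numeric(times_s)),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("projection_stack: %d frames of %d x %d px, angles [%.2f, %.2f] deg\n",
              d[3], d[1], d[2], min(x$angles_deg), max(x$angles_deg)))
  invisible(x)
}

n_frames <- function(stack) dim(stack$pixels)[3]

get_projection <- function(stack, i) {
  projection2d(stack$pixels[, , i],
               set_angle(stack$geometry, stack$angles_deg[i]),
               frame_index = i, time_s = stack$times_s[i])
}

#' Gantry sweep schedule
#'
#' Evenly spaces `n_frames` gantry angles over the arc described by `geom`
#' (inclusive of both endpoints) and assigns frame times at a fixed frame
#' rate, time zero at the first frame.
#'
#' @param geom a [cone_beam_geometry()]; `arc_start_deg`/`arc_span_deg` are used.
#' @param n_frames number of frames (>= 1).
#' @param frame_rate_hz frame rate (frames per second).
#' @return data.frame with columns `frame`, `angle_deg`, `time_s`.
#' @export
make_arc <- function(geom, n_frames, frame_rate_hz = 5.5) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (geom$arc_span_deg <= 0) stop("arc_span_deg must be > 0")
  angles <- if (n_frames == 1) geom$arc_start_deg else
    seq(geom$arc_start_deg, geom$arc_start_deg + geom$arc_span_deg,
        length.out = n_frames)
  data.frame(frame = seq_len(n_frames), angle_deg = angles,
             time_s = (seq_len(n_frames) - 1) / frame_rate_hz)
}

#' Perspective projection of a 3D point onto the detector
#'
#' @param p_world_mm 3-vector, world coordinates (mm).
#' @param geom a [cone_beam_geometry()].
#' @return 2-vector `c(u, v)` of detector coordinates in mm, (0, 0) at the
#'   principal point; `u` lateral, `v` along the patient SI axis.
#' @export
project_point <- function(p_world_mm, geom) {
  th <- geom$angle_deg * pi / 180
  s <- geom$sad_mm * c(-sin(th), cos(th), 0)
  d <- c(sin(th), -cos(th), 0)
  e_u <- c(cos(th), sin(th), 0)
  e_v <- c(0, 0, 1)
  r <- as.numeric(p_world_mm) - s
  depth <- sum(r * d)
  if (depth <= 1e-9)
    stop("projection undefined: point at or behind the source plane")
  c(u = sum(r * e_u), v = sum(r * e_v)) * geom$sdd_mm / depth
}
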