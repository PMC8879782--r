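#' Deformable digital thorax phantom specification
#'
#' Describes a synthetic thorax used to exercise and validate the whole
#' pipeline in place of patient data: an elliptical body, two lungs whose
#' inferior boundary is a diaphragm dome, an optional spine, and a spherical
#' tumor inside a lung. Breathing is an SI-dominant analytic displacement
#' field whose amplitude decays from the diaphragm toward the lung apex,
#' with fixed AP/LR fractions and an optional slow baseline drift.
#'
#' All lengths are in mm; the phantom is centred on the isocenter. The
#' defaults are a desk-scale preset (64^3 voxels at 4 mm) sized so the full
#' acquisition-to-evaluation chain runs in minutes on one CPU; the grid is
#' freely configurable (e.g. 176 x 228 x 256 at 1.1 mm).
#'
#' @param dim volume raster dimensions (x = LR, y = AP, z = SI).
#' @param spacing_mm voxel spacing, scalar or length 3.
#' @param body_semiaxes_mm semi-axes of the body ellipsoid.
#' @param lung_centers_mm 2 x 3 matrix of lung ellipsoid centres.
#' @param lung_semiaxes_mm semi-axes shared by both lungs.
#' @param diaphragm_apex_z_mm SI position of the diaphragm dome apex.
#' @param diaphragm_curvature_mm the dome drops by
#'   `curvature * r^2` at lateral distance `r` from the lung axis.
#' @param tumor_center_mm,tumor_radius_mm spherical tumor; must lie inside a
#'   lung.
#' @param mu_body,mu_lung,mu_tumor,mu_bone attenuation values (relative
#'   mm^-1).
#' @param include_spine add a static-geometry bone cylinder posteriorly.
#' @param spine_center_y_mm,spine_radius_mm spine cylinder description.
#' @param amp_si_mm breathing amplitude at the diaphragm apex (mm,
#'   peak-exhale to peak-inhale).
#' @param amp_ap_frac,amp_lr_frac AP and LR displacement as fixed fractions
#'   of the local SI displacement.
#' @param fade_start_z_mm,fade_end_z_mm inferior band over which motion
#'   fades smoothly to zero toward the caudal edge of the volume.
#' @param taper_inner motion is constant inside this fraction of the body
#'   ellipsoid radius and tapers smoothly (C^1) to zero at the body surface.
#' @param drift_mm_per_min linear baseline drift of the breathing motion in
#'   the SI direction (mm per minute), emulating intra-fraction baseline
#'   shifts.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(64, 64, 64), spacing_mm = 4,
                         body_semiaxes_mm = c(110, 85, 160),
                         lung_centers_mm = rbind(c(-45, 0, 30), c(45, 0, 30)),
                         lung_semiaxes_mm = c(35, 45, 55),
                         diaphragm_apex_z_mm = -5,
                         diaphragm_curvature_mm = 0.012,
                         tumor_center_mm = c(45, 0, 25), tumor_radius_mm = 10,
                         mu_body = 0.02, mu_lung = 0.005, mu_tumor = 0.025,
                         mu_bone = 0.04, include_spine = TRUE,
                         spine_center_y_mm = -55, spine_radius_mm = 12,
                         amp_si_mm = 10, amp_ap_frac = 0.3, amp_lr_frac = 0.1,
                         fade_start_z_mm = -80, fade_end_z_mm = -120,
                         taper_inner = 0.85, drift_mm_per_min = 1) {
  spec <- list(dim = as.integer(rep_len(dim, 3)),
               spacing = rep_len(as.numeric(spacing_mm), 3),
               body_semiaxes = body_semiaxes_mm,
               lung_centers = lung_centers_mm,
               lung_semiaxes = lung_semiaxes_mm,
               diaphragm_apex_z = diaphragm_apex_z_mm,
               diaphragm_curvature = diaphragm_curvature_mm,
               tumor_center = tumor_center_mm,
               tumor_radius = tumor_radius_mm,
               mu_body = mu_body, mu_lung = mu_lung, mu_tumor = mu_tumor,
               mu_bone = mu_bone, include_spine = include_spine,
               spine_center_y = spine_center_y_mm,
               spine_radius = spine_radius_mm,
               amp_si = amp_si_mm, amp_ap_frac = amp_ap_frac,
               amp_lr_frac = amp_lr_frac,
               lung_apex_z = lung_centers_mm[1, 3] + lung_semiaxes_mm[3],
               fade_start_z = fade_start_z_mm, fade_end_z = fade_end_z_mm,
               taper_inner = taper_inner,
               drift_mm_per_min = drift_mm_per_min)
  class(spec) <- "phantom_spec"
  if (any(spec$spacing <= 0)) stop("spacing must be > 0")
  if (spec$amp_si < 0 || spec$amp_ap_frac < 0 || spec$amp_lr_frac < 0)
    stop("amplitudes must be >= 0")
  if (any(c(mu_body, mu_lung, mu_tumor, mu_bone) < 0))
    stop("attenuations must be >= 0")
  if (spec$tumor_radius > 0 && !tumor_in_lung(spec))
    stop("phantom spec error: tumor must lie inside a lung")
  spec
}

tumor_in_lung <- function(spec) {
  p <- spec$tumor_center
  for (l in seq_len(nrow(spec$lung_centers))) {
    cen <- spec$lung_centers[l, ]
    inside <- sum(((p - cen) / spec$lung_semiaxes)^2) <= 1
    dome <- spec$diaphragm_apex_z -
      spec$diaphragm_curvature * sum((p[1:2] - cen[1:2])^2)
    if (inside && p[3] > dome) return(TRUE)
  }
  FALSE
}

# SI amplitude profile: 1 below the diaphragm apex, smooth (C^1) decay to 0
# at the lung apex, smooth fade-out toward the caudal volume edge.
si_weight <- function(spec, z) {
  w <- numeric(length(z))
  up <- z >= spec$diaphragm_apex_z & z < spec$lung_apex_z
  w[up] <- cos(pi / 2 * (z[up] - spec$diaphragm_apex_z) /
                 (spec$lung_apex_z - spec$diaphragm_apex_z))^2
  w[z >= spec$fade_start_z & z < spec$diaphragm_apex_z] <- 1
  lo <- z >= spec$fade_end_z & z < spec$fade_start_z
  w[lo] <- cos(pi / 2 * (spec$fade_start_z - z[lo]) /
                 (spec$fade_start_z - spec$fade_end_z))^2
  w
}

# smooth membership taper: 1 well inside the body ellipsoid, 0 outside it
body_taper <- function(spec, rho) {
  b <- numeric(length(rho))
  b[rho <= spec$taper_inner] <- 1
  mid <- rho > spec$taper_inner & rho < 1
  b[mid] <- cos(pi / 2 * (rho[mid] - spec$taper_inner) /
                  (1 - spec$taper_inner))^2
  b
}

grid_coords <- function(spec) {
  org <- -(spec$dim - 1) / 2 * spec$spacing
  list(x = org[1] + (seq_len(spec$dim[1]) - 1) * spec$spacing[1],
       y = org[2] + (seq_len(spec$dim[2]) - 1) * spec$spacing[2],
       z = org[3] + (seq_len(spec$dim[3]) - 1) * spec$spacing[3],
       origin = org)
}

#' Build the reference (peak-exhale) phantom volume
#'
#' Rasterises the piecewise-constant attenuation phantom at its reference
#' (peak-exhale, zero-displacement) state, together with the tumor voxel
#' mask.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` ([volume3d()]), `tumor_mask` (logical
#'   array; voxel centres within the tumor radius), `tumor_center` (mm) and
#'   `spec`.
#' @export
make_phantom <- function(spec) {
  g <- grid_coords(spec)
  nx <- spec$dim[1]; ny <- spec$dim[2]; nz <- spec$dim[3]
  X <- array(g$x, spec$dim)
  Y <- array(rep(g$y, each = nx), spec$dim)
  Z <- array(rep(g$z, each = nx * ny), spec$dim)

  mu <- array(0, spec$dim)
  body <- (X / spec$body_semiaxes[1])^2 + (Y / spec$body_semiaxes[2])^2 +
    (Z / spec$body_semiaxes[3])^2 <= 1
  mu[body] <- spec$mu_body
  if (spec$include_spine) {
    spine <- body & (X^2 + (Y - spec$spine_center_y)^2 <= spec$spine_radius^2)
    mu[spine] <- spec$mu_bone
  }
  for (l in seq_len(nrow(spec$lung_centers))) {
    cen <- spec$lung_centers[l, ]
    ell <- ((X - cen[1]) / spec$lung_semiaxes[1])^2 +
      ((Y - cen[2]) / spec$lung_semiaxes[2])^2 +
      ((Z - cen[3]) / spec$lung_semiaxes[3])^2 <= 1
    dome <- spec$diaphragm_apex_z -
      spec$diaphragm_curvature * ((X - cen[1])^2 + (Y - cen[2])^2)
    mu[ell & Z > dome] <- spec$mu_lung
  }
  tumor <- array(FALSE, spec$dim)
  if (spec$tumor_radius > 0) {
    tumor <- (X - spec$tumor_center[1])^2 + (Y - spec$tumor_center[2])^2 +
      (Z - spec$tumor_center[3])^2 <= spec$tumor_radius^2
    mu[tumor] <- spec$mu_tumor
  }
  list(volume = volume3d(mu, spec$spacing, g$origin), tumor_mask = tumor,
       tumor_center = spec$tumor_center, spec = spec)
}

#' Quasi-periodic breathing surrogate signal
#'
#' A raised-cosine breathing trace `s(t) = ((1 - cos(2 pi t / T)) / 2)^k`
#' in `[0, 1]` (0 = peak-exhale, 1 = peak-inhale), with optional seeded
#' cycle-to-cycle amplitude jitter and an optional dimensionless linear
#' drift. The shape exponent `k` controls the exhale dwell (k > 1 gives the
#' longer rest near exhale typical of free breathing).
#'
#' @param n_frames number of samples.
#' @param frame_rate_hz sampling rate; matches the acquisition frame rate.
#' @param period_s breathing period T (s).
#' @param shape_k shape exponent k (>= 1).
#' @param amplitude_jitter standard deviation of the per-cycle amplitude
#'   factor (0 = perfectly periodic).
#' @param drift_per_min dimensionless linear drift added to the signal.
#' @param seed RNG seed for the jitter; required for reproducibility when
#'   `amplitude_jitter > 0`.
#' @return object of class `respiratory_signal`: list with `values`,
#'   `times_s`, `params`.
#' @export
breathing_signal <- function(n_frames, frame_rate_hz = 5.5, period_s = 4,
                             shape_k = 2, amplitude_jitter = 0.05,
                             drift_per_min = 0, seed = NULL) {
  if (period_s <= 0) stop("period must be > 0")
  t <- (seq_len(n_frames) - 1) / frame_rate_hz
  raw <- ((1 - cos(2 * pi * t / period_s)) / 2)^shape_k
  cyc <- floor(t / period_s)
  amp <- rep(1, max(cyc) + 1)
  if (amplitude_jitter > 0) {
    amp <- with_seed(seed, pmax(0, stats::rnorm(max(cyc) + 1, 1,
                                                amplitude_jitter)))
  }
  s <- pmin(pmax(raw * amp[cyc + 1], 0), 1)
  respiratory_signal(s + drift_per_min * t / 60, t,
                     params = list(period_s = period_s, shape_k = shape_k,
                                   amplitude_jitter = amplitude_jitter,
                                   drift_per_min = drift_per_min,
                                   frame_rate_hz = frame_rate_hz, seed = seed))
}

#' Respiratory signal container
#'
#' @param values per-frame signal samples (phantom signals live in `[0, 1]`
#'   before drift; extracted traces are in arbitrary units).
#' @param times_s per-frame time stamps.
#' @param params free-form parameter list.
#' @export
respiratory_signal <- function(values, times_s, params = list()) {
  if (length(values) != length(times_s))
    stop("values and times must have equal length")
  structure(list(values = as.numeric(values), times_s = as.numeric(times_s),
                 params = params), class = "respiratory_signal")
}

#' Ground-truth displacement field at a breathing state
#'
#' The analytic motion of the phantom at signal value `s`, in the
#' reference-sampling (pull-back) convention of [warp_volume()]: the SI
#' component is `(A_SI * s + drift) * w(z) * b(p)` where `w` decays smoothly
#' from 1 at the diaphragm apex to 0 at the lung apex and `b` tapers the
#' field to zero at the body surface; AP/LR components are fixed fractions
#' of the breathing SI component. A positive SI component displaces the
#' imaged anatomy inferiorly, as the diaphragm does during inhale.
#'
#' @param spec a [phantom_spec()].
#' @param s breathing signal value (0 = peak-exhale, 1 = peak-inhale).
#' @param drift_mm baseline drift displacement to add to the SI amplitude.
#' @param wb precomputed amplitude-weight array from [gt_weight_array()]
#'   (an optimisation for frame loops; computed on the fly when `NULL`).
#' @return a [dvf()] on the phantom grid.
#' @export
ground_truth_dvf <- function(spec, s, drift_mm = 0, wb = NULL) {
  stopifnot(is.finite(s))
  g <- grid_coords(spec)
  if (is.null(wb)) wb <- gt_weight_array(spec)
  dz <- (spec$amp_si * s + drift_mm) * wb
  breath <- spec$amp_si * s * wb
  field <- array(0, c(spec$dim, 3L))
  field[, , , 1] <- spec$amp_lr_frac * breath
  field[, , , 2] <- spec$amp_ap_frac * breath
  field[, , , 3] <- dz
  dvf(field, spec$spacing, g$origin,
      provenance = sprintf("phantom ground truth, s = %.4f, drift = %.3f mm",
                           s, drift_mm))
}

# spatial amplitude profile w(z) * b(p) rasterised on the phantom grid
gt_weight_array <- function(spec) {
  g <- grid_coords(spec)
  nx <- spec$dim[1]; ny <- spec$dim[2]
  X <- array(g$x, spec$dim)
  Y <- array(rep(g$y, each = nx), spec$dim)
  Z <- array(rep(g$z, each = nx * ny), spec$dim)
  rho <- sqrt((X / spec$body_semiaxes[1])^2 + (Y / spec$body_semiaxes[2])^2 +
                (Z / spec$body_semiaxes[3])^2)
  array(si_weight(spec, as.vector(Z)) * body_taper(spec, as.vector(rho)),
        spec$dim)
}

# analytic displacement at arbitrary points (m x 3), same field as above
gt_displacement_points <- function(spec, pts, s, drift_mm = 0) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  rho <- sqrt((pts[, 1] / spec$body_semiaxes[1])^2 +
                (pts[, 2] / spec$body_semiaxes[2])^2 +
                (pts[, 3] / spec$body_semiaxes[3])^2)
  wb <- si_weight(spec, pts[, 3]) * body_taper(spec, rho)
  breath <- spec$amp_si * s * wb
  cbind(spec$amp_lr_frac * breath, spec$amp_ap_frac * breath,
        (spec$amp_si * s + drift_mm) * wb)
}

# true tumor position: invert the pull-back field at the reference centroid
# (solve p + D(p) = c by fixed-point iteration)
gt_tumor_position <- function(spec, s, drift_mm = 0) {
  cen <- spec$tumor_center
  p <- cen
  for (it in 1:25) {
    d <- gt_displacement_points(spec, p, s, drift_mm)[1, ]
    p_new <- cen - d
    if (max(abs(p_new - p)) < 1e-10) { p <- p_new; break }
    p <- p_new
  }
  p
}

#' Simulate a cone-beam acquisition of the breathing phantom
#'
#' For every frame the reference phantom is deformed by the ground-truth
#' field at that frame's breathing state (including baseline drift accrued
#' by the frame time) and forward-projected at the frame's gantry angle.
#' Optional additive Gaussian detector noise is seeded for bit
#' reproducibility. The per-frame true tumor position is returned alongside.
#'
#' @param spec a [phantom_spec()].
#' @param signal a [respiratory_signal()]; one sample per frame.
#' @param geom a [cone_beam_geometry()].
#' @param arc schedule from [make_arc()]; must match the signal length.
#' @param noise_sd additive Gaussian noise standard deviation, in the units
#'   of the line integrals (0 disables noise).
#' @param seed RNG seed for the noise.
#' @param step_mm projector ray step (default: half the smallest voxel).
#' @return list: `stack` ([projection_stack()]), `truth` (data.frame with
#'   frame, time_s, s, drift_mm and true tumor x/y/z in mm), `reference`
#'   (output of [make_phantom()]) and `signal`.
#' @export
simulate_acquisition <- function(spec, signal, geom, arc, noise_sd = 0,
                                 seed = NULL, step_mm = NULL) {
  nf <- nrow(arc)
  if (length(signal$values) != nf)
    stop("arc length and signal length differ")
  ref <- make_phantom(spec)
  if (is.null(step_mm)) step_mm <- min(spec$spacing) / 2
  px <- array(0, c(geom$detector_rows, geom$detector_cols, nf))
  truth <- matrix(0, nf, 3)
  drift <- spec$drift_mm_per_min * arc$time_s / 60
  wb <- gt_weight_array(spec)
  for (i in seq_len(nf)) {
    D <- ground_truth_dvf(spec, signal$values[i], drift[i], wb = wb)
    warped <- warp_volume(ref$volume, D)
    g <- set_angle(geom, arc$angle_deg[i])
    px[, , i] <- forward_project_cpp(as.vector(warped$voxels),
                                     dim(warped$voxels), warped$spacing,
                                     warped$origin, g$sad_mm, g$sdd_mm,
                                     g$pixel_mm, g$detector_rows,
                                     g$detector_cols, g$angle_deg, step_mm)
    truth[i, ] <- gt_tumor_position(spec, signal$values[i], drift[i])
  }
  if (noise_sd > 0)
    px <- px + with_seed(seed, array(stats::rnorm(length(px), 0, noise_sd),
                                     dim(px)))
  list(stack = projection_stack(px, geom, arc$angle_deg, arc$time_s),
       truth = data.frame(frame = arc$frame, time_s = arc$time_s,
                          s = signal$values, drift_mm = drift,
                          x = truth[, 1], y = truth[, 2], z = truth[, 3]),
       reference = ref, signal = signal)
}

# evaluate code with a temporary RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
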