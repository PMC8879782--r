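# Shared fixtures: everything is generated in code at test time.

# small geometry used across projector tests
small_geom <- function(angle = 0, nr = 24, nc = 24, pixel = 6) {
  cone_beam_geometry(detector_rows = nr, detector_cols = nc,
                     pixel_mm = pixel, angle_deg = angle)
}

# homogeneous cube, attenuation 1 mm^-1, side 20 mm, centred at isocenter.
# Spacing 1.25 mm places the cube faces exactly half a voxel beyond the
# last inside voxel centre, so the trilinear interpolant integrates to the
# analytic chord length along axis-aligned rays.
cube_volume <- function(d = 32, sp = 1.25, half = 10) {
  g <- (seq_len(d) - (d + 1) / 2) * sp
  A <- array(0, c(d, d, d))
  inside <- abs(g) <= half
  A[inside, inside, inside] <- 1.0
  volume3d(A, sp)
}

# smoothed random "texture" volume: gives demons gradient information
# everywhere (piecewise-constant images are blind in flat regions)
textured_volume <- function(d = 40, sp = 4, seed = 7, sigma_vox = 1.5,
                            lo = 0, hi = 0.02) {
  set.seed(seed)
  A <- array(rnorm(d^3), c(d, d, d))
  A <- array(fluorovol:::gauss_smooth_cpp(A, c(d, d, d), rep(sigma_vox, 3)), c(d, d, d))
  A <- (A - min(A)) / (max(A) - min(A)) * (hi - lo) + lo
  volume3d(A, sp)
}

# independent fixed-step ray-march line integral for a single detector
# pixel: pure R, re-deriving the geometry from first principles
oracle_ray_integral <- function(vol, geom, row, col, step = 0.1) {
  th <- geom$angle_deg * pi / 180
  S <- geom$sad_mm * c(-sin(th), cos(th), 0)
  dax <- c(sin(th), -cos(th), 0)
  e_u <- c(cos(th), sin(th), 0)
  e_v <- c(0, 0, 1)
  u <- (col - (geom$detector_cols + 1) / 2) * geom$pixel_mm
  v <- (row - (geom$detector_rows + 1) / 2) * geom$pixel_mm
  pix <- S + geom$sdd_mm * dax + u * e_u + v * e_v
  w <- (pix - S) / sqrt(sum((pix - S)^2))
  d <- dim(vol$voxels)
  lo <- vol$origin
  hi <- vol$origin + (d - 1) * vol$spacing
  t0 <- 0; t1 <- 2 * geom$sdd_mm
  for (a in 1:3) {
    if (abs(w[a]) < 1e-12) {
      if (S[a] < lo[a] || S[a] > hi[a]) return(0)
    } else {
      tt <- sort(c((lo[a] - S[a]) / w[a], (hi[a] - S[a]) / w[a]))
      t0 <- max(t0, tt[1]); t1 <- min(t1, tt[2])
    }
  }
  if (t1 <= t0) return(0)
  ts <- seq(t0 + step / 2, t1, by = step)
  pts <- t(S + outer(w, ts))
  vals <- fluorovol:::sample_volume_cpp(as.vector(vol$voxels), d, vol$spacing,
                            vol$origin, pts)
  sum(vals) * step
}

# analytic training set for motion-model tests: breathing + drift factors
phantom_training_dvfs <- function(spec,
                                  s = c(0, 0.1, 0.3, 0.55, 0.8, 1),
                                  drift = c(0, 0.2, 0.35, 0.5, 0.8, 1)) {
  mapply(function(si, di) ground_truth_dvf(spec, si, di), s, drift,
         SIMPLIFY = FALSE)
}

# one place to cache expensive shared fixtures across test files
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

# a short phantom acquisition (20 s of breathing, 110 frames) shared by
# the respiratory/reconstruction tests
mini_acquisition <- function() {
  cached("mini_acq", {
    spec <- phantom_spec(drift_mm_per_min = 0)
    geom <- cone_beam_geometry(detector_rows = 96, detector_cols = 96,
                               pixel_mm = 4)
    n <- 110
    sig <- breathing_signal(n, 5.5, period_s = 4, shape_k = 2,
                            amplitude_jitter = 0, seed = 11)
    arc <- make_arc(geom, n, 5.5)
    sim <- simulate_acquisition(spec, sig, geom, arc)
    list(spec = spec, geom = geom, sig = sig, arc = arc, sim = sim)
  })
}

# shared estimator scene: analytic phantom, rank-2 motion model
est_scene <- function() {
  cached("est_scene", {
    spec <- phantom_spec()
    ph <- make_phantom(spec)
    model <- build_pca_model(phantom_training_dvfs(spec), 3)
    geom <- cone_beam_geometry(detector_rows = 96, detector_cols = 96,
                               pixel_mm = 4, angle_deg = 30)
    roi <- make_roi(geom, rbind(spec$tumor_center,
                                c(spec$tumor_center[1], 0,
                                  spec$diaphragm_apex_z)), 30)
    list(spec = spec, ph = ph, f0 = ph$volume, model = model, geom = geom,
         roi = roi)
  })
}

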