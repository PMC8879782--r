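# a small 1 mm phantom whose tumor sphere fits the grid, for voxel-count
# and centroid checks
fine_spec <- function(tumor_radius = 10) {
  phantom_spec(dim = c(64, 64, 64), spacing_mm = 1,
               body_semiaxes_mm = c(40, 35, 60),
               lung_centers_mm = rbind(c(-15, 0, 5), c(15, 0, 5)),
               lung_semiaxes_mm = c(14, 16, 25),
               diaphragm_apex_z_mm = -15, diaphragm_curvature_mm = 0.01,
               tumor_center_mm = c(15, 0, 5), tumor_radius_mm = tumor_radius,
               include_spine = FALSE, amp_si_mm = 6,
               fade_start_z_mm = -24, fade_end_z_mm = -31,
               drift_mm_per_min = 0)
}

test_that("tumor mask voxelisation matches the analytic sphere volume", {
  ph0 <- make_phantom(fine_spec(tumor_radius = 0))
  expect_equal(sum(ph0$tumor_mask), 0)

  ph <- make_phantom(fine_spec(tumor_radius = 10))
  expect_lt(abs(sum(ph$tumor_mask) - 4 / 3 * pi * 10^3) / (4 / 3 * pi * 1e3),
            0.03)
  # tumor voxels are the brightest structure
  expect_equal(max(ph$volume$voxels), ph$spec$mu_tumor)
})

test_that("the phantom grid is freely configurable (clinical-scale raster)", {
  spec <- phantom_spec(dim = c(176, 228, 256), spacing_mm = 1.1)
  expect_equal(spec$dim, c(176L, 228L, 256L))
  g <- fluorovol:::grid_coords(spec)
  expect_equal(length(g$x), 176)
  expect_equal(diff(g$z)[1], 1.1)
  expect_error(phantom_spec(tumor_center_mm = c(0, 0, 0)), "inside a lung")
})

test_that("breathing signal follows its closed form and frame budget", {
  # k = 1, T = 4 s: exact raised cosine
  s <- breathing_signal(23, frame_rate_hz = 5.5, period_s = 4, shape_k = 1,
                        amplitude_jitter = 0)
  t <- (0:22) / 5.5
  expect_equal(s$values, (1 - cos(2 * pi * t / 4)) / 2, tolerance = 1e-12)
  expect_equal(s$values[1], 0)
  # T = 4 s at 5.5 fps: 22-frame period
  expect_equal(4 * 5.5, 22)
  expect_equal(s$values[23], s$values[1], tolerance = 1e-12)
  # 4 minutes at 5.5 fps: 1320 samples
  expect_length(breathing_signal(4 * 60 * 5.5, 5.5,
                                 amplitude_jitter = 0)$values, 1320)
  # jitter is seed-reproducible
  a <- breathing_signal(50, 5.5, amplitude_jitter = 0.1, seed = 4)
  b <- breathing_signal(50, 5.5, amplitude_jitter = 0.1, seed = 4)
  expect_identical(a$values, b$values)
})

test_that("ground-truth field matches its analytic form", {
  spec <- phantom_spec(drift_mm_per_min = 0)
  expect_true(all(ground_truth_dvf(spec, 0)$field == 0))

  D <- ground_truth_dvf(spec, 1)
  # at the diaphragm apex the SI displacement equals the full amplitude
  apex <- c(spec$tumor_center[1], 0, spec$diaphragm_apex_z)
  expect_equal(fluorovol:::gt_displacement_points(spec, apex, 1)[1, 3],
               spec$amp_si, tolerance = 1e-6)
  # tumor-centre displacement is A_SI * s * w(z_tumor) exactly
  for (s in c(0.25, 0.6, 1)) {
    w <- fluorovol:::si_weight(spec, spec$tumor_center[3])
    got <- fluorovol:::gt_displacement_points(spec, spec$tumor_center, s)[1, 3]
    expect_equal(got, spec$amp_si * s * w, tolerance = 1e-12)
  }
  # interpolating the rasterised field reproduces the analytic values
  pts <- rbind(spec$tumor_center, apex, c(0, -40, -60))
  expect_equal(fluorovol:::sample_dvf(D, pts),
               fluorovol:::gt_displacement_points(spec, pts, 1),
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("warping with a ground-truth field conserves mass and tracks the tumor", {
  # mass plausibility on the default study phantom at full amplitude
  spec_d <- phantom_spec(drift_mm_per_min = 0)
  ph_d <- make_phantom(spec_d)
  for (s in c(0.5, 1)) {
    warped <- warp_volume(ph_d$volume, ground_truth_dvf(spec_d, s))
    expect_lt(abs(sum(warped$voxels) - sum(ph_d$volume$voxels)) /
                sum(ph_d$volume$voxels), 0.02)
  }
  # tumor-truth consistency on the fine (1 mm) grid
  spec <- fine_spec()
  ph <- make_phantom(spec)
  for (s in c(0.5, 1)) {
    D <- ground_truth_dvf(spec, s)
    mask <- volume3d(ph$tumor_mask * 1.0, spec$spacing)
    wm <- warp_volume(mask, D)
    cen <- fluorovol:::mask_centroid(wm)
    truth <- fluorovol:::gt_tumor_position(spec, s)
    expect_lt(max(abs(cen - truth)), 0.5 * max(spec$spacing))
  }
})

test_that("acquisition simulation is consistent and reproducible", {
  spec <- fine_spec()
  geom <- cone_beam_geometry(detector_rows = 48, detector_cols = 48,
                             pixel_mm = 4)
  n <- 8
  arc <- make_arc(geom, n, 5.5)
  static <- respiratory_signal(rep(0, n), arc$time_s)
  sim <- simulate_acquisition(spec, static, geom, arc)
  ref <- make_phantom(spec)
  # static signal, no noise: every frame equals the reference projection
  for (i in c(1, 4, 8)) {
    pr <- forward_project(ref$volume,
                          fluorovol:::set_angle(geom, arc$angle_deg[i]))
    expect_identical(sim$stack$pixels[, , i], pr$pixels)
  }
  # frames recompute bit-for-bit through the independent warp+project path
  sig <- breathing_signal(n, 5.5, amplitude_jitter = 0)
  sim2 <- simulate_acquisition(spec, sig, geom, arc)
  i <- 5
  D <- ground_truth_dvf(spec, sig$values[i], 0)
  pr <- forward_project(warp_volume(ref$volume, D),
                        fluorovol:::set_angle(geom, arc$angle_deg[i]))
  expect_identical(sim2$stack$pixels[, , i], pr$pixels)
  # seeded noise is bit-reproducible
  na <- simulate_acquisition(spec, sig, geom, arc, noise_sd = 0.05, seed = 9)
  nb <- simulate_acquisition(spec, sig, geom, arc, noise_sd = 0.05, seed = 9)
  expect_identical(na$stack$pixels, nb$stack$pixels)
  expect_error(simulate_acquisition(spec, static, geom, make_arc(geom, 3, 5.5)),
               "length")
})
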