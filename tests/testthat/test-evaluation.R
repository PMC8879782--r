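test_that("tumor position maps the centroid through the field consistently", {
  spec <- phantom_spec(drift_mm_per_min = 0)
  ph <- make_phantom(spec)
  cen <- spec$tumor_center
  # zero field: the reference centroid itself
  expect_equal(tumor_position(dvf = fluorovol:::zero_dvf(ph$volume),
                              ref_centroid_mm = cen), cen)
  # uniform +5 mm SI pull-back field: anatomy (and centroid) shifts by -5
  f <- array(0, c(spec$dim, 3)); f[, , , 3] <- 5
  p <- tumor_position(dvf = dvf(f, spec$spacing), ref_centroid_mm = cen)
  expect_equal(abs(p[3] - cen[3]), 5)
  expect_equal(p, cen - c(0, 0, 5))
  # agreement with the intensity-weighted centroid of the warped mask
  D <- ground_truth_dvf(spec, 0.8)
  p2 <- tumor_position(dvf = D, ref_centroid_mm = cen)
  wm <- warp_volume(volume3d(ph$tumor_mask * 1.0, spec$spacing), D)
  expect_lt(max(abs(p2 - fluorovol:::mask_centroid(wm))),
            0.5 * max(spec$spacing))
  expect_error(tumor_position(dvf = D, ref_centroid_mm = c(0, 0, 1e4)),
               "outside")
})

test_that("detector errors scale back to isocenter by SAD/SDD", {
  g <- cone_beam_geometry(sad_mm = 1000, sdd_mm = 1536)
  p <- c(12, -30, 48)
  uv <- project_point(p, g)
  expect_equal(detector_error_at_isocenter(p, uv, g), 0)
  # 15.36 mm discrepancy on the panel is 10 mm inside the patient
  expect_equal(detector_error_at_isocenter(p, uv + c(0, -15.36), g), 10)
  # lateral discrepancies are ignored (SI-only error)
  expect_equal(detector_error_at_isocenter(p, uv + c(99, 0), g), 0)
  # composing with project_point of an SI-displaced point cancels the
  # magnification exactly
  for (dz in c(-7, 3, 12)) {
    uv2 <- project_point(c(0, 0, 10), g)
    err <- detector_error_at_isocenter(c(0, 0, 10 + dz), uv2, g)
    expect_equal(err, dz, tolerance = 1e-12)
  }
})

test_that("MAE and p95 follow their definitions", {
  r <- mae_and_p95(c(1, -2, 3))
  expect_equal(r$mae, 2)
  # order-statistic interpolation oracle for the 95th percentile
  set.seed(6)
  e <- rnorm(100)
  r2 <- mae_and_p95(e)
  a <- sort(abs(e))
  h <- 0.95 * (100 - 1) + 1
  oracle <- a[floor(h)] + (h - floor(h)) * (a[floor(h) + 1] - a[floor(h)])
  expect_equal(r2$p95, oracle)
  expect_equal(r2$mae, mean(abs(e)))
  expect_error(mae_and_p95(numeric(0)), "no errors")
})

test_that("diaphragm regression recovers a linear tumor-diaphragm relation", {
  # identical coordinates train to the identity map
  d <- seq(-20, 20, length.out = 30)
  fit0 <- fit_diaphragm_regression(d, d)
  expect_equal(unname(fit0$fits[[1]]$coefficients), c(0, 1), tolerance = 1e-9)
  # tumor_SI = 0.6 * diaphragm_SI + 3 with 0.5 mm noise, n = 200
  set.seed(14)
  dia <- runif(200, -25, 25)
  tum <- 0.6 * dia + 3 + rnorm(200, 0, 0.5)
  fit <- fit_diaphragm_regression(dia, tum)
  slope <- fit$fits[[1]]$coefficients[2]
  expect_gt(slope, 0.55); expect_lt(slope, 0.65)
  pred <- apply_regression(fit, dia)
  expect_gt(cor(pred, tum), 0.99)
  expect_error(fit_diaphragm_regression(rep(1, 10), rnorm(10)),
               "zero variance")
  expect_error(fit_diaphragm_regression(1, 1), "at least 2")
})

test_that("the diaphragm apex is detected and tracks breathing", {
  acq <- mini_acquisition()
  st <- acq$sim$stack
  # apex SI difference between exhale and inhale frames ~ A_SI x mag
  i_ex <- which.min(acq$sig$values)
  i_in <- which.max(acq$sig$values)
  a_ex <- detect_diaphragm_apex(fluorovol:::get_projection(st, i_ex))
  a_in <- detect_diaphragm_apex(fluorovol:::get_projection(st, i_in))
  mag <- st$geometry$sdd_mm / st$geometry$sad_mm
  expected <- acq$spec$amp_si * mag
  # 10 % of the true excursion, plus the detection quantisation of the
  # coarse 4 mm detector pixels
  expect_lt(abs(abs(a_ex[2] - a_in[2]) - expected),
            0.1 * expected + 1.5 * st$geometry$pixel_mm)
  # the apex trace follows the breathing signal
  v <- vapply(seq_len(110), function(i)
    detect_diaphragm_apex(fluorovol:::get_projection(st, i))[2], numeric(1))
  expect_gte(abs(cor(v, acq$sig$values)), 0.9)
  # regression from apex to projected tumor position. Under a rotating
  # gantry the apex-tumor detector relation is only approximately affine
  # (magnification differs between the two depths and changes with angle),
  # so the rotating-arc check is r >= 0.9; on a static gantry the relation
  # is affine and the regression must be nearly exact.
  tum_v <- vapply(seq_len(110), function(i) {
    g <- fluorovol:::set_angle(st$geometry, st$angles_deg[i])
    project_point(as.numeric(acq$sim$truth[i, c("x", "y", "z")]), g)[2]
  }, numeric(1))
  # both detector coordinates as predictors: the lateral coordinate carries
  # the angle information the SI coordinate alone cannot
  uvm <- t(vapply(seq_len(110), function(i)
    detect_diaphragm_apex(fluorovol:::get_projection(st, i)), numeric(2)))
  fit <- fit_diaphragm_regression(uvm, tum_v)
  pred <- apply_regression(fit, uvm)
  expect_gte(cor(pred, tum_v), 0.9)

  # static-gantry sequence: breathing is the only factor
  spec0 <- acq$spec
  geom0 <- st$geometry
  sig0 <- breathing_signal(44, 5.5, 4, 2, amplitude_jitter = 0, seed = 3)
  arc0 <- make_arc(geom0, 44, 5.5)
  arc0$angle_deg <- rep(0, 44)
  sim0 <- simulate_acquisition(spec0, sig0, geom0, arc0)
  v0 <- vapply(seq_len(44), function(i)
    detect_diaphragm_apex(fluorovol:::get_projection(sim0$stack, i))[2],
    numeric(1))
  tum0 <- vapply(seq_len(44), function(i)
    project_point(as.numeric(sim0$truth[i, c("x", "y", "z")]),
                  geom0)[2], numeric(1))
  fit0s <- fit_diaphragm_regression(v0, tum0)
  expect_gte(cor(apply_regression(fit0s, v0), tum0), 0.95)
  # featureless projections cannot contain a diaphragm
  flat <- projection2d(matrix(1, 96, 96), acq$geom)
  expect_error(detect_diaphragm_apex(flat), "no diaphragm")
})
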