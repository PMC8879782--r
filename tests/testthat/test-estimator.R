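test_that("ROI masks cover the projected landmarks and reject off-panel ones", {
  sc <- est_scene()
  expect_true(any(sc$roi))
  uv <- project_point(sc$spec$tumor_center, sc$geom)
  r <- round(uv[2] / sc$geom$pixel_mm + (96 - 1) / 2) + 1
  c_ <- round(uv[1] / sc$geom$pixel_mm + (96 - 1) / 2) + 1
  expect_true(sc$roi[r, c_])
  expect_error(make_roi(sc$geom, c(5000, 0, 0)), "outside the panel|behind")
})

test_that("rendering composes the documented operators with no shortcuts", {
  sc <- est_scene()
  u <- sc$model$scores[4, ]
  r1 <- render_projection(u, sc$f0, sc$model, sc$geom)
  # independent composition path
  r2 <- forward_project(warp_volume(sc$f0, reconstruct_dvf(sc$model, u)),
                        sc$geom)
  expect_lt(max(abs(r1$pixels - r2$pixels)) / max(abs(r2$pixels)), 1e-6)
  # near-zero coefficients and mean: rendering ~ projection of f0
  spec0 <- phantom_spec(drift_mm_per_min = 0)
  m0 <- build_pca_model(lapply(c(0, 1e-9), function(s)
    ground_truth_dvf(spec0, s)), 1)
  ph0 <- make_phantom(spec0)
  r0 <- render_projection(0, ph0$volume, m0, sc$geom)
  expect_lt(max(abs(r0$pixels - forward_project(ph0$volume, sc$geom)$pixels)) /
              max(r0$pixels), 1e-6)
})

test_that("lambda is the closed-form least-squares intensity scale", {
  sc <- est_scene()
  x <- forward_project(sc$f0, sc$geom)
  expect_equal(estimate_lambda(x, x, sc$roi), 1)
  scaled <- projection2d(2.5 * x$pixels, sc$geom)
  expect_equal(estimate_lambda(scaled, x, sc$roi), 2.5, tolerance = 1e-12)
  # random pair: matches a brute-force 1-D scan of the objective
  set.seed(21)
  r <- projection2d(matrix(rnorm(96^2), 96, 96), sc$geom)
  m <- projection2d(matrix(rnorm(96^2), 96, 96), sc$geom)
  lam <- estimate_lambda(r, m, sc$roi)
  grid_l <- seq(lam - 0.5, lam + 0.5, length.out = 2001)
  J <- vapply(grid_l, function(l)
    sum(((r$pixels - l * m$pixels)[sc$roi])^2), numeric(1))
  expect_lt(abs(grid_l[which.min(J)] - lam), 1e-3)  # grid resolution limit
  expect_gt(min(J), sum(((r$pixels - lam * m$pixels)[sc$roi])^2) - 1e-9)
  zero <- projection2d(matrix(0, 96, 96), sc$geom)
  expect_error(estimate_lambda(r, zero, sc$roi), "degenerate ROI")
})

test_that("the analytic gradient matches central finite differences", {
  sc <- est_scene()
  u_meas <- sc$model$scores[4, ]
  x <- render_projection(u_meas, sc$f0, sc$model, sc$geom)
  set.seed(42)
  worst <- 0
  for (rep in 1:10) {
    u <- sc$model$scores[sample(6, 1), ] + rnorm(sc$model$n_modes, 0, 15)
    cg <- cost_and_gradient(u, sc$f0, sc$model, sc$geom, x, sc$roi)
    h <- 1e-2
    for (i in seq_along(u)) {
      up <- u; up[i] <- u[i] + h
      um <- u; um[i] <- u[i] - h
      fd <- (fluorovol:::cost_only(up, sc$f0, sc$model, sc$geom, x, sc$roi, 2) -
               fluorovol:::cost_only(um, sc$f0, sc$model, sc$geom, x, sc$roi, 2)) /
        (2 * h)
      worst <- max(worst, abs(cg$gradient[i] - fd) / max(abs(fd), 1e-8))
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("cost is zero at a perfect fit and invariant to joint scaling", {
  sc <- est_scene()
  u <- sc$model$scores[3, ]
  x <- render_projection(u, sc$f0, sc$model, sc$geom)
  cg <- cost_and_gradient(u, sc$f0, sc$model, sc$geom, x, sc$roi)
  scale <- sum((x$pixels[sc$roi])^2)
  expect_lt(cg$cost / scale, 1e-20)
  expect_lt(sqrt(sum(cg$gradient^2)), 1e-8 * scale)
  expect_equal(cg$lambda, 1, tolerance = 1e-12)
  # scaling x by c is absorbed by the closed-form lambda: J unchanged
  u2 <- u + 12
  x3 <- projection2d(3 * x$pixels, sc$geom)
  J1 <- fluorovol:::cost_only(u2, sc$f0, sc$model, sc$geom, x, sc$roi, 2)
  J3 <- fluorovol:::cost_only(u2, sc$f0, sc$model, sc$geom, x3, sc$roi, 2)
  expect_equal(J1, J3, tolerance = 1e-9)
})

test_that("single-frame estimation recovers in-span states (inverse crime)", {
  sc <- est_scene()
  # u_true = 0 with x = P f(0): stays at zero
  x0 <- render_projection(rep(0, sc$model$n_modes), sc$f0, sc$model, sc$geom)
  e0 <- estimate_frame(x0, sc$f0, sc$model, sc$geom, roi = sc$roi)
  expect_lt(max(abs(e0$u)) / sqrt(sc$model$eigenvalues[1]), 1e-6)
  # a state inside the training range
  u_true <- 0.7 * sc$model$scores[5, ] + 0.3 * sc$model$scores[4, ]
  x <- render_projection(u_true, sc$f0, sc$model, sc$geom)
  est <- suppressWarnings(estimate_frame(x, sc$f0, sc$model, sc$geom,
                                         roi = sc$roi))
  # monotone descent along the accepted iterates
  expect_true(all(diff(est$state$cost_history) <= 1e-12))
  tp_t <- tumor_position(model = sc$model, u = u_true,
                         ref_centroid_mm = sc$spec$tumor_center)
  tp_e <- tumor_position(model = sc$model, u = est$u,
                         ref_centroid_mm = sc$spec$tumor_center)
  expect_lt(abs(tp_t[3] - tp_e[3]), min(sc$spec$spacing))  # < 1 voxel SI
})

test_that("sequence estimation warm-starts and tolerates modest noise", {
  sc <- est_scene()
  geom0 <- cone_beam_geometry(detector_rows = 96, detector_cols = 96,
                              pixel_mm = 4)
  nfr <- 6
  arc <- make_arc(geom0, nfr, 5.5)
  u_true <- sc$model$scores[c(1, 2, 4, 6, 4, 2), ]
  px <- array(0, c(96, 96, nfr))
  for (i in seq_len(nfr))
    px[, , i] <- render_projection(u_true[i, ], sc$f0, sc$model,
                                   fluorovol:::set_angle(geom0,
                                                         arc$angle_deg[i]))$pixels
  stack <- projection_stack(px, geom0, arc$angle_deg, arc$time_s)
  lm_ <- rbind(sc$spec$tumor_center,
               c(sc$spec$tumor_center[1], 0, sc$spec$diaphragm_apex_z))
  est <- suppressWarnings(estimate_sequence(stack, sc$f0, sc$model,
                                            roi_landmarks_mm = lm_,
                                            ref_centroid_mm =
                                              sc$spec$tumor_center))
  expect_equal(nrow(est$coefficients), nfr)   # one state per frame
  z_true <- vapply(seq_len(nfr), function(i)
    tumor_position(model = sc$model, u = u_true[i, ],
                   ref_centroid_mm = sc$spec$tumor_center)[3], numeric(1))
  mae0 <- mean(abs(est$tumor_mm[, 3] - z_true))
  expect_lt(mae0, min(sc$spec$spacing))
  # additive noise at 2 % of the projection maximum: degradation < 1 voxel
  set.seed(77)
  noisy <- projection_stack(px + array(rnorm(length(px), 0,
                                             0.02 * max(px)), dim(px)),
                            geom0, arc$angle_deg, arc$time_s)
  estn <- suppressWarnings(estimate_sequence(noisy, sc$f0, sc$model,
                                             roi_landmarks_mm = lm_,
                                             ref_centroid_mm =
                                               sc$spec$tumor_center))
  maen <- mean(abs(estn$tumor_mm[, 3] - z_true))
  expect_lt(maen - mae0, min(sc$spec$spacing))
})
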