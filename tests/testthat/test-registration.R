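test_that("warping obeys identity, uniform shifts and an independent oracle", {
  vol <- textured_volume(d = 24, sp = 2, seed = 5)
  # zero field: identical bit-for-bit
  expect_identical(warp_volume(vol, fluorovol:::zero_dvf(vol))$voxels,
                   vol$voxels)
  # uniform +2 voxel SI shift of a linear SI ramp equals the analytic shift
  d <- 24; sp <- 2
  g <- (seq_len(d) - (d + 1) / 2) * sp
  ramp <- volume3d(array(rep(g, each = d * d), c(d, d, d)), sp)
  f <- array(0, c(d, d, d, 3)); f[, , , 3] <- 2 * sp
  wr <- warp_volume(ramp, dvf(f, sp))
  shifted <- array(rep(pmin(g + 2 * sp, max(g)), each = d * d), c(d, d, d))
  expect_lt(max(abs(wr$voxels[, , 1:(d - 2)] - shifted[, , 1:(d - 2)])), 1e-6)
  # general smooth field: agree with a plain-R trilinear oracle at random
  # voxels
  set.seed(8)
  f2 <- array(rnorm(d^3 * 3, sd = 1.5), c(d, d, d, 3))
  for (a in 1:3)
    f2[, , , a] <- array(fluorovol:::gauss_smooth_cpp(f2[, , , a],
                                                      c(d, d, d), rep(2, 3)),
                         c(d, d, d))
  D2 <- dvf(f2, sp)
  w2 <- warp_volume(vol, D2)
  idx <- cbind(sample(2:(d - 1), 40, TRUE), sample(2:(d - 1), 40, TRUE),
               sample(2:(d - 1), 40, TRUE))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, ]
    p <- vol$origin + (i - 1) * sp + f2[i[1], i[2], i[3], ]
    gidx <- pmin(pmax((p - vol$origin) / sp, 0), d - 1)
    i0 <- pmin(floor(gidx), d - 2); fr <- gidx - i0
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
      acc <- acc + vol$voxels[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1] *
        prod(abs(1 - c(dx, dy, dz) - fr))
    expect_equal(w2$voxels[i[1], i[2], i[3]], acc, tolerance = 1e-10)
  }
  expect_error(warp_volume(vol, fluorovol:::zero_dvf(ramp_to <- volume3d(
    array(0, c(8, 8, 8)), 2))), "grid mismatch")
})

test_that("registering a volume to itself returns a negligible field", {
  vol <- textured_volume(d = 24, sp = 4, seed = 9)
  D <- demons_register(vol, vol, demons_params(iterations = c(10, 10, 10)))
  expect_lt(max(abs(D$field)), 0.1 * 4)
})

test_that("demons recovers a known smooth deformation below half a voxel", {
  vol <- textured_volume(d = 40, sp = 4, seed = 7)
  d <- 40; sp <- 4
  g <- (seq_len(d) - (d + 1) / 2) * sp
  Z <- array(rep(g, each = d * d), c(d, d, d))
  # smooth 3-voxel SI deformation, tapered toward the volume edges
  f <- array(0, c(d, d, d, 3))
  f[, , , 3] <- 3 * sp * cos(pi * Z / (2 * max(g)))^2
  D_true <- dvf(f, sp)
  warped <- warp_volume(vol, D_true)
  D_est <- suppressWarnings(demons_register(warped, vol))
  epe <- sqrt(apply((D_est$field - D_true$field)^2, 1:3, sum))
  inner <- array(FALSE, c(d, d, d))
  inner[5:(d - 4), 5:(d - 4), 5:(d - 4)] <- TRUE
  expect_lt(mean(epe[inner]), 0.5 * sp)
  # registration reduced the intensity residual
  resid_before <- sqrt(mean((warped$voxels - vol$voxels)^2))
  resid_after <- sqrt(mean((warp_volume(vol, D_est)$voxels -
                              warped$voxels)^2))
  expect_lt(resid_after, resid_before)
})

test_that("the recovered field is smooth (positive Jacobian almost everywhere)", {
  vol <- textured_volume(d = 32, sp = 4, seed = 3)
  d <- 32; sp <- 4
  g <- (seq_len(d) - (d + 1) / 2) * sp
  Z <- array(rep(g, each = d * d), c(d, d, d))
  f <- array(0, c(d, d, d, 3))
  f[, , , 3] <- 8 * cos(pi * Z / (2 * max(g)))^2
  warped <- warp_volume(vol, dvf(f, sp))
  D <- suppressWarnings(demons_register(warped, vol))
  # discrete Jacobian determinant of (identity + field) along each axis
  dz <- D$field[, , , 3]
  jac <- 1 + (dz[, , 3:d] - dz[, , 1:(d - 2)]) / (2 * sp)
  expect_gte(mean(jac > 0), 0.99)
})

test_that("phase-to-reference registration follows the pull-back convention", {
  spec <- phantom_spec(drift_mm_per_min = 0)
  ph <- make_phantom(spec)
  # noiseless analytic phases (FDK bypassed)
  svals <- c(0, 0.35, 1)
  phases <- lapply(svals, function(s)
    warp_volume(ph$volume, ground_truth_dvf(spec, s)))
  dvfs <- suppressWarnings(register_all_phases(phases, 1))
  expect_length(dvfs, 3)
  expect_true(all(dvfs[[1]]$field == 0))   # reference entry is zero
  # DVF at the tumor centre within 20 % of the ground-truth magnitude
  tc <- spec$tumor_center
  for (i in 2:3) {
    est <- fluorovol:::sample_dvf(dvfs[[i]], tc)[1, ]
    truth <- fluorovol:::gt_displacement_points(spec, tc, svals[i])[1, ]
    expect_lt(abs(sqrt(sum(est^2)) - sqrt(sum(truth^2))) /
                sqrt(sum(truth^2)), 0.2)
  }
  # identical phases give near-zero fields
  same <- suppressWarnings(register_all_phases(list(ph$volume, ph$volume), 1,
                                               demons_params(iterations =
                                                               c(5, 5, 5))))
  expect_lt(max(abs(same[[2]]$field)), 0.4)
  expect_error(register_all_phases(list(ph$volume), 1), "at least 2")
})
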