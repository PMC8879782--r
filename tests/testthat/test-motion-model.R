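# small synthetic DVFs for fast, exact PCA checks
toy_dvf <- function(field, sp = 4) dvf(field, sp)

toy_grid <- c(8, 8, 8)

random_unit_field <- function(seed) {
  set.seed(seed)
  v <- rnorm(prod(toy_grid) * 3)
  array(v / sqrt(sum(v^2)), c(toy_grid, 3))
}

test_that("identical training fields give the mean and zero variance", {
  base <- array(2, c(toy_grid, 3))
  dvfs <- lapply(1:4, function(i) toy_dvf(base))
  m <- suppressWarnings(build_pca_model(dvfs, 2))
  expect_equal(m$mean, rep(2, prod(toy_grid) * 3))
  expect_lt(max(m$eigenvalues), 1e-10)
  expect_error(explained_variance(m), "eigenvalues are zero")
})

test_that("a constructed two-factor model is recovered exactly", {
  v1 <- random_unit_field(1)
  v2r <- random_unit_field(2)
  # orthonormalise v2 against v1
  v2 <- v2r - sum(v1 * v2r) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  mean_f <- array(0.5, c(toy_grid, 3))
  # zero-mean, mutually orthogonal score sequences with variance ratio 9:1
  a <- c(-3, -1, 1, 3)
  b <- c(1, -1, -1, 1) * sqrt(5) / 3
  dvfs <- lapply(1:4, function(t) toy_dvf(mean_f + a[t] * v1 + b[t] * v2))
  m <- build_pca_model(dvfs, n_modes = 3)
  expect_equal(m$n_modes, 2L)       # only two factors exist
  ev <- explained_variance(m)
  # two modes explain everything; ratios are 0.9 / 0.1 by construction
  expect_equal(ev$cumulative[2], 1, tolerance = 1e-9)
  expect_equal(ev$ratio[1:2], c(0.9, 0.1), tolerance = 1e-9)
  # recovered subspace spans {v1, v2}: principal angles ~ 0
  V <- cbind(as.vector(v1), as.vector(v2))
  sv <- svd(crossprod(V, m$modes))$d
  expect_lt(max(acos(pmin(sv, 1))), 1e-6)
})

test_that("eigenvectors are orthonormal and the spectrum is non-increasing", {
  set.seed(31)
  dvfs <- lapply(1:6, function(i)
    toy_dvf(array(rnorm(prod(toy_grid) * 3), c(toy_grid, 3))))
  m <- build_pca_model(dvfs, n_modes = 5)
  G <- crossprod(m$modes)
  expect_lt(max(abs(G - diag(5))), 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-9))
  expect_true(all(m$eigenvalues >= 0))
  # sign convention: the dominant SI entry of every mode is positive
  nv <- prod(toy_grid)
  for (i in 1:5) {
    blk <- m$modes[(2 * nv + 1):(3 * nv), i]
    expect_gt(blk[which.max(abs(blk))], 0)
  }
})

test_that("reconstruction is linear and exact with all modes", {
  set.seed(13)
  dvfs <- lapply(1:5, function(i)
    toy_dvf(array(rnorm(prod(toy_grid) * 3), c(toy_grid, 3))))
  m <- build_pca_model(dvfs, n_modes = 4)   # full rank: samples - 1
  # u = 0 gives the mean exactly
  expect_equal(as.vector(reconstruct_dvf(m, rep(0, 4))$field), m$mean)
  # training scores reproduce each training field
  for (k in c(1, 3, 5)) {
    rec <- reconstruct_dvf(m, m$scores[k, ])
    scale <- max(abs(dvfs[[k]]$field))
    expect_lt(max(abs(rec$field - dvfs[[k]]$field)) / scale, 1e-6)
  }
  # linearity: D(u) + D(-u) = 2 * mean
  u <- rnorm(4)
  s <- reconstruct_dvf(m, u)$field + reconstruct_dvf(m, -u)$field
  expect_equal(as.vector(s), 2 * m$mean, tolerance = 1e-9)
  expect_error(reconstruct_dvf(m, rep(0, 2)), "length")
})

test_that("mode count requests are truncated to samples - 1 with a warning", {
  set.seed(5)
  dvfs <- lapply(1:3, function(i)
    toy_dvf(array(rnorm(prod(toy_grid) * 3), c(toy_grid, 3))))
  expect_warning(m <- build_pca_model(dvfs, n_modes = 5), "truncating")
  expect_equal(m$n_modes, 2L)
  expect_error(build_pca_model(dvfs[1]), "at least 2")
})

test_that("phantom motion collapses onto very few modes", {
  spec <- phantom_spec()
  dvfs <- phantom_training_dvfs(spec)  # breathing + drift: 2 latent factors
  m <- build_pca_model(dvfs, 3)
  ev <- explained_variance(m)
  expect_gte(ev$cumulative[min(3, length(ev$cumulative))], 0.99)
  # scores track the breathing factor monotonically
  expect_gt(abs(cor(m$scores[, 1], c(0, 0.1, 0.3, 0.55, 0.8, 1))), 0.99)
})
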