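test_that("spatial gradients: constants, ramps, axis separation", {
  expect_true(all(unlist(spatial_gradients(const_vol(5))) == 0))
  r <- ramp_x(a = 3)
  g <- spatial_gradients(r)
  expect_equal(g$gx[, , 2:11], array(3, c(8, 10, 10)))
  expect_true(all(g$gy == 0) && all(g$gz == 0))
  ry <- image_volume(array(rep(rep(2 * 0:9, each = 8), 12), c(8, 10, 12)), c(1, 1, 1))
  gy <- spatial_gradients(ry)
  expect_true(all(gy$gx == 0) && all(gy$gz == 0))
  expect_equal(gy$gy[, 5, ], array(2, c(8, 12)))
})

test_that("single-level LK recovers a sub-voxel shift of a linear ramp", {
  d <- c(12, 16, 16)
  base <- array(rep(3 * (0:(d[3] - 1)), each = d[1] * d[2]), d)
  flt <- image_volume(base, c(1, 1, 1))
  ref <- image_volume(base + 3 * 0.5, c(1, 1, 1))  # ramp shifted +0.5 voxel in x
  f <- lk_flow_level(ref, flt, lk_params(1, 2))
  interior <- f$disp[5:8, 6:11, 6:11, ]
  expect_lt(max(abs(interior[, , , 3] - 0.5)), 1e-3)
  expect_lt(max(abs(interior[, , , 1:2])), 1e-3)
})

test_that("identical images give a zero field and flat regions are gated", {
  v <- make_smooth_phantom(shape = c(10, 24, 24), spacing = c(1, 1, 1), seed = 9)
  f <- lk_flow_level(v, v, lk_params(1, 3))
  expect_equal(max(abs(f$disp)), 0)
  # constant image: aperture-degenerate everywhere, update gated to zero
  cv <- const_vol(100, c(10, 12, 12))
  cv2 <- const_vol(100, c(10, 12, 12))
  f2 <- lk_flow_level(cv, cv2, lk_params(1, 2))
  expect_equal(max(abs(f2$disp)), 0)
})


test_that("the weighted normal equations match an explicit-loop oracle", {
  set.seed(21)
  d <- c(9, 9, 9)
  base <- array(0, d)
  iz <- array(0:8, d); iy <- array(rep(0:8, each = 9), d)
  ix <- array(rep(0:8, each = 81), d)
  for (i in 1:6) {
    c0 <- runif(3, 1, 7); s <- runif(1, 1.5, 3); a <- runif(1, -80, 80)
    base <- base + a * exp(-((iz - c0[1])^2 + (iy - c0[2])^2 + (ix - c0[3])^2) / (2 * s^2))
  }
  ref <- image_volume(base, c(1, 1, 1))
  flt <- image_volume(base + array(rnorm(prod(d), sd = 4), d), c(1, 1, 1))
  p <- lk_params(1, 2, iters_per_level = 1, stop_mean_update = 0)
  f <- lk_flow_level(ref, flt, p)
  want <- lk_oracle_once(ref, flt, r = 2, sigma = p$weight_sigma,
                         eig_factor = p$min_eigen_factor, clip = p$update_clip)
  expect_lt(max(abs(f$disp - want)), 1e-8)
})

test_that("image pyramids halve in-plane resolution and respect the slice rule", {
  v <- make_smooth_phantom(shape = c(6, 32, 32), spacing = c(2.5, 1, 1), seed = 2)
  expect_identical(build_pyramid(v, 1)[[1]], v)
  pyr <- build_pyramid(v, 2)
  expect_equal(dim(pyr[[2]]$data), c(6L, 16L, 16L))  # 6 slices: z not downsampled
  expect_equal(pyr[[2]]$spacing, c(2.5, 2, 2))
  vz <- make_smooth_phantom(shape = c(16, 32, 32), seed = 2)
  expect_equal(dim(build_pyramid(vz, 2)[[2]]$data), c(8L, 16L, 16L))
  cv <- const_vol(7, c(8, 16, 16))
  expect_true(all(abs(build_pyramid(cv, 2)[[2]]$data - 7) < 1e-12))
  expect_error(build_pyramid(v, 5), "too small")
})

test_that("translation equivariance of the recovered flow", {
  v <- make_smooth_phantom(shape = c(12, 40, 40), spacing = c(1, 1, 1), seed = 6)
  d <- dim(v$data)
  shift_x <- function(a, s) {
    out <- a
    out[, , 1:(d[3] - s)] <- a[, , (s + 1):d[3]]
    out[, , (d[3] - s + 1):d[3]] <- a[, , d[3]]
    out
  }
  ref <- v; ref$data <- shift_x(v$data, 1)
  f0 <- lk_flow_level(ref, v, lk_params(1, 2))
  # shift both images by 2 voxels: the field shifts with them (interior)
  ref2 <- v; ref2$data <- shift_x(v$data, 3)
  flt2 <- v; flt2$data <- shift_x(v$data, 2)
  f1 <- lk_flow_level(ref2, flt2, lk_params(1, 2))
  a <- f0$disp[4:9, 8:33, 8:31, ]
  b <- f1$disp[4:9, 8:33, 6:29, ]
  expect_lt(mean(abs(a - b)), 0.05)
})

test_that("pyramid registration of identical volumes stays near zero", {
  v <- make_smooth_phantom(shape = c(16, 32, 32), seed = 8)
  for (p in list(lk_params(1, 2), lk_params(2, 3), lk_params(2, 4))) {
    f <- pyramid_lk_register(v, v, p)
    n <- sqrt(apply(f$disp^2, 1:3, sum))
    expect_lt(mean(n), 0.05)
    expect_lt(max(n), 0.5)
  }
})

test_that("jacobian diagnostics flag folding fields", {
  geom <- grid_geometry(c(8, 8, 8), c(1, 1, 1))
  ok <- zero_field(geom)
  expect_equal(jacobian_report(ok)$n_negative, 0)
  bad <- zero_field(geom)
  bad$disp[, , , 3] <- array(rep(c(0, 3, 0, 3, 0, 3, 0, 3) * rep(c(1, -1), each = 4),
                                 each = 64), c(8, 8, 8))
  expect_gt(jacobian_report(bad)$n_negative, 0)
})
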