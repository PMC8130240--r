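test_that("trilinear sampling interpolates and clamps", {
  v <- const_vol(7)
  expect_equal(trilinear_sample(v, c(1.3, 2.7, 0.4)), 7)
  expect_equal(trilinear_sample(v, c(-5, 99, 2)), 7)  # edge clamp

  cube <- image_volume(array(as.numeric(0:7), c(2, 2, 2)), c(1, 1, 1))
  expect_equal(trilinear_sample(cube, c(0, 1, 1)), cube$data[1, 2, 2])
  expect_equal(trilinear_sample(cube, c(0.5, 0.5, 0.5)), mean(0:7))

  expect_error(trilinear_sample(cube, c(0, NA, 0)), "invalid coordinate")
})

test_that("trilinear sample never overshoots the corner values", {
  set.seed(42)
  v <- image_volume(array(rnorm(5 * 6 * 7), c(5, 6, 7)), c(1, 1, 1))
  p <- cbind(runif(200, -1, 5), runif(200, -1, 6), runif(200, -1, 7))
  s <- trilinear_sample(v, p)
  expect_true(all(s >= min(v$data) - 1e-12 & s <= max(v$data) + 1e-12))
})

test_that("warping with the zero field is the identity", {
  set.seed(1)
  v <- image_volume(array(rnorm(6 * 7 * 8), c(6, 7, 8)), c(2.5, 1, 1))
  w <- warp_volume(v, zero_field(v))
  expect_identical(w$data, v$data)
})

test_that("uniform integer displacement equals an array shift on the interior", {
  r <- ramp_x()
  f <- zero_field(r)
  f$disp[, , , 3] <- 1
  w <- warp_volume(r, f)
  expect_equal(w$data[, , 1:11], r$data[, , 2:12])
  # constant volume unchanged under any field
  cv <- const_vol(4, dim = dim(r$data))
  expect_equal(warp_volume(cv, f)$data, cv$data)
})

test_that("warping demands matching geometry", {
  v <- const_vol(1, dim = c(4, 4, 4))
  f <- zero_field(const_vol(1, dim = c(4, 4, 5)))
  expect_error(warp_volume(v, f), "geometry mismatch")
})

test_that("field composition handles zero and uniform fields", {
  set.seed(2)
  geom <- grid_geometry(c(6, 8, 8), c(1, 1, 1))
  z <- zero_field(geom)
  u <- zero_field(geom); u$disp[, , , 2] <- 0.7; u$disp[, , , 3] <- -0.3
  expect_equal(compose_update(z, u)$disp, u$disp)
  expect_equal(compose_update(u, z)$disp, u$disp)
  t2 <- zero_field(geom); t2$disp[, , , 2] <- -0.2; t2$disp[, , , 1] <- 0.5
  ab <- compose_update(u, t2)
  ba <- compose_update(t2, u)
  want <- u$disp + t2$disp
  expect_equal(ab$disp, want, tolerance = 1e-12)
  expect_equal(ab$disp, ba$disp, tolerance = 1e-12)
})

test_that("world/voxel conversions are mutually inverse and (z,y,x) ordered", {
  g <- grid_geometry(c(10, 20, 30), c(2.5, 1, 1), c(0, 0, 0))
  expect_equal(world_to_voxel(g, g$origin), c(0, 0, 0))
  expect_equal(world_to_voxel(g, c(5, 3, 4)), c(2, 3, 4))
  set.seed(3)
  p <- matrix(rnorm(30, sd = 20), ncol = 3)
  expect_equal(voxel_to_world(g, world_to_voxel(g, p)), p, tolerance = 1e-12)
})

test_that("container invariants are enforced", {
  expect_error(image_volume(array(1, c(2, 1, 1)), c(1, 1, 1)), "length >= 2")
  expect_error(image_volume(array(NA_real_, c(2, 2, 2)), c(1, 1, 1)), "finite")
  expect_error(dose_grid(array(-1, c(2, 2, 2)), c(1, 1, 1)), ">= 0")
  expect_error(grid_geometry(c(2, 2, 2), c(0, 1, 1)), "spacing")
  expect_error(fractionation_scheme(0, 10), "n_fractions")
  expect_error(fractionation_scheme(25, 0), "alpha_beta")
  df <- data.frame(label = c("a", "a"), ref_z = 1, ref_y = 1, ref_x = 1,
                   flt_z = 1, flt_y = 1, flt_x = 1)
  expect_error(landmark_set(df), "duplicate")
})

test_that("resampling onto the same geometry is a no-op, otherwise interpolates", {
  r <- ramp_x(a = 2)
  expect_identical(resample_to_geometry(r, geometry_of(r)), r)
  g2 <- grid_geometry(c(8, 10, 6), c(1, 1, 2), c(0, 0, 0))
  r2 <- resample_to_geometry(r, g2)
  # x world coordinate 2k maps to ramp value 2*(2k)
  expect_equal(r2$data[4, 5, ], 2 * seq(0, 10, by = 2), tolerance = 1e-12)
})
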