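test_that("rigid transforms: identity, integer shift, symmetry", {
  v <- make_smooth_phantom(shape = c(12, 32, 32), spacing = c(1, 1, 1), seed = 3)
  id <- apply_rigid(v, c(0, 0, 0), c(0, 0, 0))
  expect_equal(id$data[3:10, 5:28, 5:28], v$data[3:10, 5:28, 5:28],
               tolerance = 1e-12)

  # move content +1 voxel along x: out[.., i] = in[.., i-1] on the interior
  sh <- apply_rigid(v, c(0, 0, 1))
  expect_equal(sh$data[, , 2:32], v$data[, , 1:31], tolerance = 1e-9)

  # a 90-degree-symmetric phantom is invariant under 90-degree z rotation
  g <- grid_geometry(c(4, 21, 21), c(1, 1, 1))
  co <- expand.grid(z = 0:3, y = 0:20, x = 0:20)
  r2 <- (co$y - 10)^2 + (co$x - 10)^2
  sym <- image_volume(array(exp(-r2 / 40) * 100, c(4, 21, 21)), c(1, 1, 1))
  rot <- apply_rigid(sym, rotation_deg = c(90, 0, 0))
  expect_equal(rot$data[, 3:19, 3:19], sym$data[, 3:19, 3:19], tolerance = 1e-6)
})

test_that("affine transforms validate, invert and round-trip landmarks", {
  expect_error(affine_transform(matrix(0, 3, 3)), "singular")
  t1 <- affine_transform(matrix(c(1, 0.1, 0, 0, 0.9, 0, 0.05, 0, 1.1), 3, 3),
                         c(4, -2, 1))
  ti <- affine_invert(t1)
  expect_equal(ti$matrix %*% t1$matrix, diag(3), tolerance = 1e-12)
  lm <- landmark_set(data.frame(label = letters[1:4],
                                ref_z = rnorm(4), ref_y = rnorm(4), ref_x = rnorm(4),
                                flt_z = rnorm(4), flt_y = rnorm(4), flt_x = rnorm(4)))
  back <- apply_affine(apply_affine(lm, t1), affine_invert(t1))
  expect_equal(as.data.frame(back), as.data.frame(lm), tolerance = 1e-9)
})

test_that("pure translation of a dose grid matches the shift oracle", {
  d <- dose_grid(array(rep(seq(0, 22, 2), each = 6 * 8), c(6, 8, 12)), c(1, 1, 1))
  tr <- affine_transform(diag(3), c(0, 0, -1))  # read source 1 mm left
  out <- apply_affine(d, tr)
  expect_equal(out$data[, , 2:12], d$data[, , 1:11], tolerance = 1e-9)
})

test_that("affine self-registration is near-identity", {
  v <- make_smooth_phantom(seed = 2)
  t0 <- affine_register(v, v)
  # action on every voxel center moves < 0.25 voxel
  f <- affine_to_field(t0, geometry_of(v))
  expect_lt(max(abs(f$disp)), 0.25)
  expect_true(attr(t0, "mse_final") <= attr(t0, "mse_initial"))
})

test_that("affine registration recovers known translations and scalings", {
  flt <- make_smooth_phantom()
  ref <- apply_affine(flt, affine_transform(diag(3), c(0, 0, 8)))
  t_hat <- affine_register(ref, flt)
  expect_lt(sqrt(sum((t_hat$translation - c(0, 0, -8))^2)), 0.5)
  expect_lt(max(abs(t_hat$matrix - diag(3))), 0.01)

  cen <- c(mean(range(0:23 * 2.5)), mean(range(0:71)), mean(range(0:71)))
  Ms <- diag(3) * 1.05
  refs <- apply_affine(flt, affine_transform(Ms, cen - Ms %*% cen))
  t_s <- affine_register(refs, flt)
  expect_lt(max(abs(diag(t_s$matrix) - 1 / 1.05)), 0.01)
  # per-level metric never ends above where it started
  for (tr in attr(t_s, "mse_trace")) expect_lte(tr["final"], tr["initial"])
})

test_that("affine recovery under combined translation, rotation and scale", {
  flt <- make_smooth_phantom(seed = 4)
  cen <- ctdosemap:::world_center(flt)
  R <- ctdosemap:::rot3("z", 3)
  M <- R * 1.02
  truth <- affine_transform(M, cen - M %*% cen + c(2, -3, 4))
  ref <- apply_affine(flt, truth)
  # registering ref (floating arg) onto flt recovers the inverse transform
  t_hat <- affine_register(ref, flt)
  f_hat <- affine_to_field(t_hat, geometry_of(flt))
  f_true <- affine_to_field(affine_invert(truth), geometry_of(flt))
  err <- sqrt(apply((f_hat$disp - f_true$disp)^2, c(1, 2, 3), sum))
  expect_lt(mean(err), 0.5)
})
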