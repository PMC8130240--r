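test_that("landmark distances with and without a field", {
  lm <- landmark_set(data.frame(label = c("a", "b"),
    ref_z = c(0, 5), ref_y = c(0, 5), ref_x = c(0, 5),
    flt_z = c(0, 6), flt_y = c(0, 7), flt_x = c(0, 7)))
  res <- landmark_distance(lm)
  expect_equal(res$per_point, c(0, 3))
  expect_equal(res$mean, 1.5)
  expect_equal(res$min, 0); expect_equal(res$max, 3)

  cs <- small_case()
  # predicting through the exact generating field cancels the residual
  expect_lt(landmark_distance(cs$bundle$landmarks, cs$field)$mean, 1e-9)
  expect_gt(landmark_distance(cs$bundle$landmarks)$mean, 0.1)
  expect_error(landmark_distance(lm[0, ]), "empty")
})

test_that("masked RMSE matches hand-computed values", {
  v <- make_smooth_phantom(shape = c(8, 16, 16), seed = 5)
  m <- full_mask(v)
  expect_equal(rmse_within_mask(v, v, m), 0)
  v10 <- v; v10$data <- v$data + 10
  expect_equal(rmse_within_mask(v, v10, m), 10)
  half <- v
  sel <- array(FALSE, dim(v$data)); sel[, , 1:8] <- TRUE
  half$data[sel] <- half$data[sel] + 10
  expect_equal(rmse_within_mask(v, half, m), sqrt(50))
  empty <- structure_mask("e", array(FALSE, dim(v$data)), v$spacing)
  expect_error(rmse_within_mask(v, v, empty), "empty")
})


test_that("discretized gamma equals the exhaustive brute-force search", {
  set.seed(31)
  ref <- matrix(200 + 100 * sin(outer(1:16, 1:16, "+") / 3), 16, 16)
  ev <- ref + matrix(rnorm(256, sd = 6), 16, 16)
  mask <- matrix(TRUE, 16, 16)
  p <- gamma_params()
  got <- gamma_slice(ref, ev, mask, c(1, 1), p)
  want <- gamma_oracle(ref, ev, mask, 1, 1, p)
  expect_lt(max(abs(got$gamma_map - want), na.rm = TRUE), 1e-6)
})

test_that("gamma boundary cases: identity and the exact-2% pixel", {
  ref <- matrix(100, 8, 8)
  got <- gamma_slice(ref, ref, matrix(TRUE, 8, 8), c(1, 1))
  expect_true(all(got$gamma_map == 0))
  expect_equal(got$pass_rate_pct, 100)

  # one evaluated pixel, flat surroundings, value differs by exactly 2%
  ev <- ref; ev[] <- 102
  m1 <- matrix(FALSE, 8, 8); m1[4, 4] <- TRUE
  g1 <- gamma_slice(ref, ev, m1, c(1, 1))
  expect_equal(g1$gamma_map[4, 4], 1.0)
  expect_equal(g1$pass_rate_pct, 100)
  ev2 <- ref; ev2[] <- 102.5
  g2 <- gamma_slice(ref, ev2, m1, c(1, 1))
  expect_gt(g2$gamma_map[4, 4], 1)
  expect_equal(g2$pass_rate_pct, 0)
})

test_that("gamma invariances: global offset and local scale", {
  set.seed(32)
  ref <- matrix(150 + 60 * cos(outer(1:12, 1:12) / 9), 12, 12)
  ev <- ref + matrix(rnorm(144, sd = 4), 12, 12)
  mask <- matrix(TRUE, 12, 12)
  pg <- gamma_params(mode = "global")
  r1 <- gamma_slice(ref, ev, mask, c(1, 1), pg)
  r2 <- gamma_slice(ref + 500, ev + 500, mask, c(1, 1), pg)
  expect_equal(r1$pass_rate_pct, r2$pass_rate_pct)
  pl <- gamma_params(mode = "local")
  l1 <- gamma_slice(ref, ev, mask, c(1, 1), pl)
  l2 <- gamma_slice(3 * ref, 3 * ev, mask, c(1, 1), pl)
  expect_equal(l1$pass_rate_pct, l2$pass_rate_pct)
})

test_that("study gamma averages per-slice pass rates over evaluable slices", {
  v <- make_smooth_phantom(shape = c(8, 16, 16), seed = 7)
  m <- full_mask(v)
  expect_equal(gamma_study(v, v, m)$study_pct, 100)
  # construct a two-slice mask: one perfect slice, one fully failing slice
  v2 <- v
  v2$data[2, , ] <- v$data[2, , ] * 2 + 1000
  mask2 <- structure_mask("b", array(FALSE, dim(v$data)), v$spacing)
  mask2$mask[1:2, , ] <- TRUE
  mask2 <- structure_mask("b", mask2$mask, v$spacing)
  gs <- gamma_study(v, v2, mask2)
  expect_equal(gs$per_slice$pass_rate_pct[1], 100)
  expect_equal(gs$study_pct, mean(gs$per_slice$pass_rate_pct[1:2]))
  empty <- structure_mask("e", array(FALSE, dim(v$data)), v$spacing)
  expect_error(gamma_study(v, v, empty), "no evaluable slice")
})

test_that("D_v equals the sorted-voxel oracle and DVH is monotone", {
  # ten 1 cm^3 voxels (10 x 10 x 10 mm) with doses 1..10 Gy
  d <- dose_grid(array(rep(1:10, each = 1), c(10, 2, 2)) * 1.0, c(10, 10, 10))
  d$data[] <- rep(1:10, 4)
  m <- structure_mask("s", array(c(rep(TRUE, 10), rep(FALSE, 30)), c(10, 2, 2)),
                      c(10, 10, 10))
  expect_equal(dose_at_volume(d, m, 2), 9)
  expect_equal(dose_at_volume(d, m, 0.5), 10)
  expect_equal(dose_at_volume(d, m, 10), 1)
  expect_error(dose_at_volume(d, m, 11), "exceeds structure volume")

  u <- d; u$data[] <- 4.2
  for (v_cm3 in c(0.5, 2, 9)) expect_equal(dose_at_volume(u, m, v_cm3), 4.2)

  set.seed(33)
  dr <- dose_grid(array(runif(80, 0, 60), c(4, 4, 5)), c(5, 5, 5))
  mr <- structure_mask("r", array(runif(80) < 0.6, c(4, 4, 5)), c(5, 5, 5))
  vox <- prod(dr$spacing) / 1000
  doses <- sort(dr$data[mr$mask], decreasing = TRUE)
  vs <- c(0.2, 0.5, 1, 2)
  for (v_cm3 in vs) {
    expect_identical(dose_at_volume(dr, mr, v_cm3), doses[ceiling(v_cm3 / vox)])
  }
  expect_true(all(diff(vapply(vs, function(v) dose_at_volume(dr, mr, v), 0)) <= 0))
  curve <- dvh(dr, mr)
  expect_true(all(diff(curve$volume_frac) <= 0))
  expect_equal(curve$volume_frac[1], 1)
})

test_that("DVH addition versus DIR accumulation", {
  # identical distributions, zero field: exact equality
  set.seed(34)
  a <- dose_grid(array(runif(125, 10, 50), c(5, 5, 5)), c(10, 10, 10))
  m <- structure_mask("o", array(TRUE, c(5, 5, 5)), c(10, 10, 10))
  cmp0 <- compare_accumulation(a, a, zero_field(a), m, v_cm3 = c(0.5, 2))
  expect_equal(cmp0$added_gy, cmp0$dir_gy)

  # deliberately misaligned multi-voxel hot regions: addition overestimates
  e <- dose_grid(array(1, c(5, 5, 5)), c(10, 10, 10)); e$data[1:2, 1:2, 1] <- 60
  b <- dose_grid(array(1, c(5, 5, 5)), c(10, 10, 10)); b$data[4:5, 4:5, 5] <- 55
  cmp1 <- compare_accumulation(e, b, zero_field(e), m, v_cm3 = c(0.5, 2))
  expect_true(all(cmp1$added_gy > cmp1$dir_gy))
  # sorted-voxel oracle on the same toy inputs
  accum <- e$data + b$data
  for (i in 1:2) {
    k <- ceiling(cmp1$v_cm3[i] / 1)
    expect_equal(cmp1$dir_gy[i], sort(accum, decreasing = TRUE)[k])
    expect_equal(cmp1$added_gy[i],
                 sort(e$data, decreasing = TRUE)[k] + sort(b$data, decreasing = TRUE)[k])
  }
})
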