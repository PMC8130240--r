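test_that("EQD2 reproduces the hand-evaluated conversions", {
  # 2 Gy per fraction is the fixed point for any alpha/beta
  for (ab in c(3, 10)) {
    sch <- fractionation_scheme(10, ab)
    expect_equal(eqd2(20, sch), 20)
  }
  expect_equal(eqd2(45, fractionation_scheme(25, 10)), 45 * (10 + 1.8) / 12)
  expect_equal(eqd2(45, fractionation_scheme(25, 10)), 44.25)
  expect_equal(eqd2(28, fractionation_scheme(4, 3)), 28 * (3 + 7) / 5)
  expect_equal(eqd2(28, fractionation_scheme(4, 3)), 56)
})

test_that("EQD2 is monotone and straddles the 2 Gy fixed point", {
  sch <- fractionation_scheme(25, 10)
  D <- seq(0, 80, by = 0.5)
  e <- eqd2(D, sch)
  expect_true(all(diff(e) > 0))
  expect_true(all(e[D > 50] > D[D > 50]))   # d > 2 Gy -> EQD2 > D
  expect_true(all(e[D < 50 & D > 0] < D[D < 50 & D > 0]))
  # grid conversion matches scalar conversion voxelwise
  g <- dose_grid(array(runif(60, 0, 80), c(3, 4, 5)), c(1, 1, 1))
  expect_equal(eqd2(g, sch)$data, eqd2(g$data, sch))
})

test_that("dose mapping shares warping semantics and edge behavior", {
  d <- dose_grid(array(rep(seq(0, 33, 3), each = 48), c(6, 8, 12)), c(1, 1, 1))
  expect_equal(map_dose(d, zero_field(d))$data, d$data)
  f <- zero_field(d); f$disp[, , , 3] <- 1
  expect_equal(map_dose(d, f)$data[, , 1:11], d$data[, , 2:12])
  cd <- dose_grid(array(5, c(6, 8, 12)), c(1, 1, 1))
  f$disp[, , , 2] <- -2.3
  expect_equal(map_dose(cd, f)$data, cd$data)
  expect_error(map_dose(dose_grid(array(0, c(6, 8, 11)), c(1, 1, 1)), f),
               "geometry mismatch")
})

test_that("accumulation is commutative and matches scalar sums", {
  a <- dose_grid(array(44.25, c(3, 3, 3)), c(1, 1, 1))
  b <- dose_grid(array(56, c(3, 3, 3)), c(1, 1, 1))
  expect_equal(unique(as.numeric(accumulate_dose(a, b)$data)), 100.25)
  set.seed(4)
  x <- dose_grid(array(runif(27), c(3, 3, 3)), c(1, 1, 1))
  y <- dose_grid(array(runif(27), c(3, 3, 3)), c(1, 1, 1))
  expect_equal(accumulate_dose(x, y)$data, accumulate_dose(y, x)$data)
  zero <- x; zero$data[] <- 0
  expect_equal(accumulate_dose(x, zero)$data, x$data)
})

test_that("landmark dose averages the six face neighbors", {
  d <- dose_grid(array(0, c(5, 5, 5)), c(1, 1, 1))
  expect_equal(landmark_dose(d, c(2, 2, 2)), 0)
  u <- dose_grid(array(7.5, c(5, 5, 5)), c(1, 1, 1))
  expect_equal(landmark_dose(u, c(2.2, 1.8, 2.4)), 7.5)
  # neighbors valued 1..6, center voxel deliberately different
  nb <- dose_grid(array(0, c(5, 5, 5)), c(1, 1, 1))
  nb$data[3, 3, 3] <- 99
  nb$data[2, 3, 3] <- 1; nb$data[4, 3, 3] <- 2
  nb$data[3, 2, 3] <- 3; nb$data[3, 4, 3] <- 4
  nb$data[3, 3, 2] <- 5; nb$data[3, 3, 4] <- 6
  expect_equal(landmark_dose(nb, c(2, 2, 2)), 3.5)
  # linear ramp: symmetric neighbors cancel to the center value
  r <- dose_grid(array(rep(2 * 0:4, each = 25), c(5, 5, 5)), c(1, 1, 1))
  expect_equal(landmark_dose(r, c(2, 2, 2)), r$data[3, 3, 3])
  expect_error(landmark_dose(d, c(99, 0, 0)), "outside")
})

test_that("dose difference report: zero field, aggregation, self-consistency", {
  cs <- small_case(); b <- cs$bundle
  sch_e <- fractionation_scheme(25, 10, 45)
  sch_b <- fractionation_scheme(4, 10, 28)
  ee <- eqd2(b$floating_dose, sch_e)
  eb <- eqd2(b$reference_dose, sch_b)

  # identical points in both frames + zero field: before equals after
  pts <- voxel_to_world(geometry_of(b$reference_ct),
                        cbind(c(6, 8), c(20, 24), c(20, 28)))
  lm_same <- landmark_set(data.frame(label = c("p1", "p2"),
    ref_z = pts[, 1], ref_y = pts[, 2], ref_x = pts[, 3],
    flt_z = pts[, 1], flt_y = pts[, 2], flt_x = pts[, 3]))
  rep0 <- dose_difference_report(lm_same, ee, eb,
                                 zero_field(geometry_of(b$reference_ct)))
  expect_equal(rep0$per_landmark$dose_before_gy, rep0$per_landmark$dose_after_gy)

  # summary rows aggregate the per-landmark table
  rept <- dose_difference_report(b$landmarks, ee, eb, cs$field)
  expect_equal(rept$summary$mean_abs_diff_gy, mean(rept$per_landmark$abs_diff_gy))
  expect_equal(rept$summary$mean_rel_diff_pct, mean(rept$per_landmark$rel_diff_pct))
  expect_equal(rept$summary$range_abs_diff_gy, range(rept$per_landmark$abs_diff_gy))

  # under the ground-truth field the differences sit at the interpolation floor
  expect_lt(rept$summary$mean_abs_diff_gy, 0.2)
  expect_error(dose_difference_report(lm_same[0, ], ee, eb, cs$field), "empty")
})
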