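test_that("case generation is deterministic under the seed", {
  a <- make_case(small_spec())
  b <- make_case(small_spec())
  expect_identical(a$bundle$reference_ct$data, b$bundle$reference_ct$data)
  expect_identical(a$bundle$floating_ct$data, b$bundle$floating_ct$data)
  expect_identical(a$field$disp, b$field$disp)
  expect_identical(as.data.frame(a$bundle$landmarks),
                   as.data.frame(b$bundle$landmarks))
  c2 <- make_case(small_spec(seed = 2))
  expect_false(identical(a$bundle$floating_ct$data, c2$bundle$floating_ct$data))
})

test_that("deformation fields are sums of bumps with positive Jacobian", {
  sp <- small_spec()
  f <- make_field(sp)
  b1 <- sp$bumps[[1]]
  at <- f$disp[b1$center[1] + 1, b1$center[2] + 1, b1$center[3] + 1, ]
  expect_equal(at, b1$amp, tolerance = 1e-12)
  expect_equal(jacobian_report(f)$n_negative, 0)
  sp0 <- small_spec(bumps = list())
  expect_true(all(make_field(sp0)$disp == 0))
  expect_error(phantom_spec(bumps = list(list(center = c(8, 24, 24),
                                              amp = c(0, 6, 0), width = 10))),
               "amplitude")
})

test_that("zero-amplitude deformation leaves anatomy in place", {
  sp <- small_spec(bumps = list(), noise_sigma_hu = 0)
  cs <- make_case(sp)
  b <- cs$bundle
  rods <- b$masks$applicator_ref$mask
  expect_identical(b$reference_ct$data[!rods], b$floating_ct$data[!rods])
  expect_true(all(b$reference_ct$data[rods] == sp$applicator$hu))
  lm <- b$landmarks
  expect_equal(unname(as.matrix(lm[, 2:4])), unname(as.matrix(lm[, 5:7])))
})

test_that("landmark pairs are exactly consistent with the field", {
  cs <- small_case()
  g <- geometry_of(cs$field)
  v <- world_to_voxel(g, as.matrix(cs$bundle$landmarks[, 2:4]))
  disp <- vapply(1:3, function(k)
    trilinear_sample(list(data = cs$field$disp[, , , k],
                          spacing = g$spacing, origin = g$origin), v),
    numeric(nrow(v)))
  pred <- voxel_to_world(g, v + disp)
  expect_lt(max(abs(pred - as.matrix(cs$bundle$landmarks[, 5:7]))), 1e-6)
})

test_that("requesting more landmarks than high-gradient voxels errors", {
  expect_error(make_case(small_spec(n_landmarks = 100000L)), "high-gradient")
})

test_that("bundle carries doses, masks and fractionation in both frames", {
  cs <- small_case(); b <- cs$bundle
  expect_s3_class(b$floating_dose, "dose_grid")
  expect_s3_class(b$reference_dose, "dose_grid")
  expect_true(all(c("body_ref", "body_flt", "bladder_ref", "bladder_flt",
                    "applicator_ref") %in% names(b$masks)))
  expect_equal(b$fractionation$ebrt$n_fractions, 25L)
  expect_equal(b$fractionation$brt$n_fractions, 4L)
  # BRT dose is capped and steepest near the applicator
  expect_lte(max(b$reference_dose$data), cs$spec$brt_cap_gy)
  rod_zone <- dilate_mask(b$masks$applicator_ref, 3)$mask
  expect_gt(mean(b$reference_dose$data[rod_zone]),
            mean(b$reference_dose$data[!rod_zone]))
})
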