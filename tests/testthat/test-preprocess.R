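test_that("dilation uses a Euclidean ball in voxel units", {
  m <- array(FALSE, c(7, 7, 7)); m[4, 4, 4] <- TRUE
  sm <- structure_mask("a", m, c(1, 1, 1))
  d1 <- dilate_mask(sm, 1)
  expect_equal(sum(d1$mask), 7)  # face-connected cross
  expect_true(all(which(d1$mask, arr.ind = TRUE) %in% 3:5))

  # r = 2 against a brute-force sweep of all offsets
  d2 <- dilate_mask(sm, 2)
  want <- array(FALSE, c(7, 7, 7))
  for (dz in -2:2) for (dy in -2:2) for (dx in -2:2)
    if (dz^2 + dy^2 + dx^2 <= 4) want[4 + dz, 4 + dy, 4 + dx] <- TRUE
  expect_equal(d2$mask, want)

  full <- structure_mask("f", array(TRUE, c(3, 3, 3)), c(1, 1, 1))
  expect_equal(dilate_mask(full, 2)$mask, full$mask)
  empty <- structure_mask("e", array(FALSE, c(3, 3, 3)), c(1, 1, 1))
  expect_true(dilate_mask(empty, 1)$empty)
})

test_that("applicator in-painting draws within mean +/- 200 HU of the ring", {
  set.seed(11)
  ct <- image_volume(array(40 + rnorm(16 * 16 * 16, sd = 5), c(16, 16, 16)),
                     c(1, 1, 1))
  m <- array(FALSE, c(16, 16, 16)); m[6:10, 6:10, 6:10] <- TRUE
  mask <- structure_mask("applicator", m, c(1, 1, 1))
  ring <- dilate_mask(mask, 2)$mask & !m
  mring <- mean(ct$data[ring])

  # no blur: every in-painted voxel within the stated band
  p0 <- inpaint_params(blur_sigma_mm = 0, seed = 5)
  out0 <- replace_applicator(ct, mask, p0)
  expect_true(all(out0$data[m] >= mring - 200 & out0$data[m] <= mring + 200))
  expect_identical(out0$data[!m], ct$data[!m])

  # with blur: untouched outside the one-ring dilation, still inside the band
  p1 <- inpaint_params(seed = 5)
  out1 <- replace_applicator(ct, mask, p1)
  region <- dilate_mask(mask, 1)$mask
  expect_identical(out1$data[!region], ct$data[!region])
  lo <- min(c(out0$data[region], ct$data[region]))
  hi <- max(c(out0$data[region], ct$data[region]))
  expect_true(all(out1$data[region] >= lo - 1e-9 & out1$data[region] <= hi + 1e-9))
})

test_that("in-painting is seed-reproducible and seed-sensitive", {
  ct <- image_volume(array(40, c(12, 12, 12)), c(1, 1, 1))
  m <- array(FALSE, c(12, 12, 12)); m[5:8, 5:8, 5:8] <- TRUE
  mask <- structure_mask("a", m, c(1, 1, 1))
  a <- replace_applicator(ct, mask, inpaint_params(seed = 1))
  b <- replace_applicator(ct, mask, inpaint_params(seed = 1))
  c3 <- replace_applicator(ct, mask, inpaint_params(seed = 2))
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c3$data))
  region <- dilate_mask(mask, 1)$mask
  expect_identical(a$data[!region], c3$data[!region])
  # constant 40 HU tissue: band is [-160, 240] exactly
  nb <- replace_applicator(ct, mask, inpaint_params(blur_sigma_mm = 0, seed = 3))
  expect_true(all(nb$data[m] >= -160 & nb$data[m] <= 240))
})

test_that("degenerate in-painting inputs error", {
  ct <- image_volume(array(0, c(6, 6, 6)), c(1, 1, 1))
  empty <- structure_mask("e", array(FALSE, c(6, 6, 6)), c(1, 1, 1))
  expect_error(replace_applicator(ct, empty), "empty")
  all_m <- structure_mask("a", array(TRUE, c(6, 6, 6)), c(1, 1, 1))
  expect_error(replace_applicator(ct, all_m), "ring")
})

test_that("RNG state of the session is not disturbed", {
  ct <- image_volume(array(40, c(8, 8, 8)), c(1, 1, 1))
  m <- array(FALSE, c(8, 8, 8)); m[4:5, 4:5, 4:5] <- TRUE
  mask <- structure_mask("a", m, c(1, 1, 1))
  set.seed(99); before <- .Random.seed
  invisible(replace_applicator(ct, mask, inpaint_params(seed = 7)))
  expect_identical(.Random.seed, before)
})
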