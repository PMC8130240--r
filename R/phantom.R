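# Deterministic synthetic-case generator: CT-like pelvic phantom pairs
# related by a known smooth deformation, EBRT/BRT-like dose grids, organ
# masks, applicator rods and consistent landmark pairs. This is the test
# bed on which every registration and accumulation property is evaluated.

#' Phantom specification
#'
#' Defines one synthetic case. The floating (EBRT-frame) CT is an analytic
#' pelvis: soft-tissue body, bone and organ ellipsoids, plus a smooth
#' random HU texture inside the body (deformable registration needs
#' intensity structure away from edges). The reference (BRT-frame) CT is
#' the floating CT warped through a known sum-of-Gaussian-bumps
#' deformation, with high-HU applicator rods stamped in. Both get
#' independent Gaussian HU noise.
#'
#' @param shape grid size `(nz, ny, nx)` in voxels.
#' @param spacing voxel size mm, default `(2.5, 1, 1)` (CT slice thickness
#'   2.5 mm, ~1 mm in-plane).
#' @param hu named HU levels per tissue.
#' @param noise_sigma_hu additive Gaussian noise sigma.
#' @param texture_bands list of texture bands, each
#'   `list(n =, amp_hu =, sigma_mm = c(lo, hi))`: `n` Gaussian blobs with
#'   amplitudes uniform in `+/- amp_hu` and widths uniform in `sigma_mm`,
#'   summed inside the body. Multiple bands give the soft tissue structure
#'   at several spatial scales.
#' @param applicator list: `n_rods`, `radius_mm`, `hu`, `half_length_mm`,
#'   `x_offsets_mm` (rod positions about the pelvic center).
#' @param bumps list of deformation bumps, each
#'   `list(center = voxel (z,y,x), amp = voxels (dz,dy,dx), width = voxels)`;
#'   amplitudes must stay below `width / 2` so the field remains smooth and
#'   invertible in practice.
#' @param ebrt_plateau_gy EBRT plateau level (physical Gy); the plateau is
#'   wide, so the in-field dose is nearly uniform as for a whole-pelvis
#'   prescription.
#' @param ebrt_boost list describing the smooth boost component riding on
#'   the plateau (`center_offset_mm` from the volume center, `amp_gy`,
#'   `sigma_mm`); deliberately offset from the applicator so the EBRT and
#'   BRT hot spots do not coincide anatomically.
#' @param brt_d10_gy BRT dose at 10 mm from the source cluster (physical
#'   Gy); the BRT grid is a capped inverse-square falloff around the rods.
#' @param brt_cap_gy cap on the BRT dose.
#' @param n_landmarks landmark pairs sampled at high-gradient voxels.
#' @param seed integer; fixed seed gives byte-identical cases.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64L, 128L, 128L), spacing = c(2.5, 1, 1),
                         hu = c(air = -1000, soft = 40, bone = 700,
                                bladder = 10, rectum = -60),
                         noise_sigma_hu = 10,
                         texture_bands = list(
                           list(n = 60L, amp_hu = 120, sigma_mm = c(10, 18)),
                           list(n = 100L, amp_hu = 80, sigma_mm = c(2.5, 6))),
                         applicator = list(n_rods = 3L, radius_mm = 3,
                                           hu = 1500, half_length_mm = 35,
                                           x_offsets_mm = c(-8, 0, 8)),
                         bumps = list(
                           list(center = c(32, 52, 64), amp = c(0.5, 3.5, 1.0), width = 18),
                           list(center = c(32, 76, 54), amp = c(-0.5, -2.5, 2.0), width = 20),
                           list(center = c(20, 64, 74), amp = c(1.0, 1.5, -2.5), width = 18),
                           list(center = c(40, 64, 30), amp = c(0.5, 1.0, 2.8), width = 16),
                           list(center = c(24, 60, 100), amp = c(-0.5, 2.0, -1.5), width = 16)),
                         ebrt_plateau_gy = 45,
                         ebrt_boost = list(center_offset_mm = c(15, -10, 25),
                                           amp_gy = 9, sigma_mm = 25),
                         brt_d10_gy = 28,
                         brt_cap_gy = 60, n_landmarks = 60L, seed = 1L) {
  for (b in bumps)
    if (sqrt(sum(b$amp^2)) >= b$width / 2)
      stop("bump amplitude must be < width/2 to keep the field smooth")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 hu = hu, noise_sigma_hu = noise_sigma_hu,
                 texture_bands = texture_bands,
                 applicator = applicator, bumps = bumps,
                 ebrt_plateau_gy = ebrt_plateau_gy, ebrt_boost = ebrt_boost,
                 brt_d10_gy = brt_d10_gy,
                 brt_cap_gy = brt_cap_gy, n_landmarks = as.integer(n_landmarks),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# world-coordinate arrays for a geometry; returned as list(Z, Y, X)
coord_arrays <- function(geom) {
  geom <- geometry_of(geom)
  d <- geom$dim
  z <- geom$origin[1] + (seq_len(d[1]) - 1) * geom$spacing[1]
  y <- geom$origin[2] + (seq_len(d[2]) - 1) * geom$spacing[2]
  x <- geom$origin[3] + (seq_len(d[3]) - 1) * geom$spacing[3]
  list(Z = array(z, d),
       Y = array(rep(y, each = d[1]), d),
       X = array(rep(x, each = d[1] * d[2]), d))
}

ellipsoid <- function(co, center, semi) {
  ((co$Z - center[1]) / semi[1])^2 + ((co$Y - center[2]) / semi[2])^2 +
    ((co$X - center[3]) / semi[3])^2 <= 1
}

#' Build the ground-truth deformation field of a phantom
#'
#' `disp(x) = sum_k a_k exp(-|x - c_k|^2 / (2 w_k^2))` in voxel units, with
#' the all-voxel Jacobian determinant of `x + disp(x)` verified positive.
#'
#' @param spec a [phantom_spec()].
#' @return A [deformation_field()].
#' @export
make_field <- function(spec) {
  d <- spec$shape
  disp <- array(0, c(d, 3L))
  iz <- array(seq_len(d[1]) - 1, d)
  iy <- array(rep(seq_len(d[2]) - 1, each = d[1]), d)
  ix <- array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), d)
  for (b in spec$bumps) {
    g <- exp(-((iz - b$center[1])^2 + (iy - b$center[2])^2 +
                 (ix - b$center[3])^2) / (2 * b$width^2))
    for (k in 1:3) disp[, , , k] <- disp[, , , k] + b$amp[k] * g
  }
  field <- deformation_field(disp, spec$spacing)
  jr <- jacobian_report(field)
  if (jr$n_negative > 0)
    stop(sprintf("deformation folds (min Jacobian %.3f); reduce bump amplitudes",
                 jr$min_jacobian))
  field
}

#' Generate a synthetic case with ground truth
#'
#' Builds the full [case_bundle()] -- both CTs, organ and applicator masks
#' in both frames, EBRT and BRT dose grids, paired landmarks -- together
#' with the ground-truth deformation field relating the frames. Landmarks
#' are sampled at high-gradient voxels of the reference anatomy (away from
#' the applicator and the volume border) and paired exactly through the
#' field. Fully deterministic under `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return List with `bundle` (a `case_bundle`), `field` (ground truth) and
#'   `spec`.
#' @export
make_case <- function(spec) {
  d <- spec$shape
  geom <- grid_geometry(d, spec$spacing)
  co <- coord_arrays(geom)
  cen <- world_center(geom)
  hu <- spec$hu

  organs <- list(
    body = ellipsoid(co, cen, c(0.95 * (d[1] - 1) * spec$spacing[1] / 2,
                                0.82 * (d[2] - 1) * spec$spacing[2] / 2,
                                0.92 * (d[3] - 1) * spec$spacing[3] / 2)),
    bone_l = ellipsoid(co, cen + c(0, 8, -40), c(28, 14, 12)),
    bone_r = ellipsoid(co, cen + c(0, 8, 40), c(28, 14, 12)),
    sacrum = ellipsoid(co, cen + c(0, 32, 0), c(35, 12, 14)),
    bladder = ellipsoid(co, cen + c(0, -22, 0), c(24, 18, 18)),
    rectum = ellipsoid(co, cen + c(0, 25, 0), c(40, 9, 9)))

  paint <- array(hu[["air"]], d)
  paint[organs$body] <- hu[["soft"]]
  paint[organs$bone_l | organs$bone_r | organs$sacrum] <- hu[["bone"]]
  paint[organs$bladder] <- hu[["bladder"]]
  paint[organs$rectum] <- hu[["rectum"]]

  texture <- array(0, d)
  with_local_seed(spec$seed, {
    # multi-scale HU texture inside the body
    bbox_lo <- cen - c(50, 40, 45); bbox_hi <- cen + c(50, 40, 45)
    for (band in spec$texture_bands) {
      for (i in seq_len(band$n)) {
        c_i <- stats::runif(3, bbox_lo, bbox_hi)
        a_i <- stats::runif(1, -band$amp_hu, band$amp_hu)
        s_i <- stats::runif(1, band$sigma_mm[1], band$sigma_mm[2])
        texture <- texture + a_i * exp(-((co$Z - c_i[1])^2 + (co$Y - c_i[2])^2 +
                                           (co$X - c_i[3])^2) / (2 * s_i^2))
      }
    }
    flt_clean <- paint + texture * organs$body
    flt_ct <- image_volume(flt_clean + stats::rnorm(length(flt_clean),
                                                    0, spec$noise_sigma_hu),
                           spec$spacing)

    field <- make_field(spec)
    ref_clean <- warp_volume(image_volume(flt_clean, spec$spacing), field)$data

    ap <- spec$applicator
    rods <- array(FALSE, d)
    for (xo in ap$x_offsets_mm[seq_len(ap$n_rods)]) {
      rods <- rods | ((co$Y - cen[2])^2 + (co$X - (cen[3] + xo))^2 <= ap$radius_mm^2 &
                        abs(co$Z - cen[1]) <= ap$half_length_mm)
    }
    ref_with_rods <- ref_clean
    ref_with_rods[rods] <- ap$hu
    ref_ct <- image_volume(ref_with_rods + stats::rnorm(length(ref_with_rods),
                                                        0, spec$noise_sigma_hu),
                           spec$spacing)

    # masks: analytic in the floating frame, pulled to the reference frame
    warp_ind <- function(ind) {
      w <- warp_volume(image_volume(array(as.numeric(ind), d) * 2 - 1,
                                    spec$spacing), field)
      w$data > 0
    }
    masks <- list()
    for (nm in c("body", "bladder", "rectum")) {
      masks[[paste0(nm, "_flt")]] <- structure_mask(nm, organs[[nm]], spec$spacing)
      masks[[paste0(nm, "_ref")]] <- structure_mask(nm, warp_ind(organs[[nm]]),
                                                    spec$spacing)
    }
    masks$applicator_ref <- structure_mask("applicator", rods, spec$spacing)

    # landmarks at high-gradient voxels of the (clean, rod-free) reference
    g <- cpp_gradients(as.numeric(ref_clean), d)
    gm <- array(sqrt(g$gz^2 + g$gy^2 + g$gx^2), d)
    rod_zone <- dilate_mask(masks$applicator_ref, 6L)$mask
    iz <- array(seq_len(d[1]) - 1, d)
    iy <- array(rep(seq_len(d[2]) - 1, each = d[1]), d)
    ix <- array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), d)
    interior <- iz >= 4 & iz <= d[1] - 5 & iy >= 8 & iy <= d[2] - 9 &
      ix >= 8 & ix <= d[3] - 9
    cand <- which(masks$body_ref$mask & !rod_zone & interior &
                    gm > stats::quantile(gm[masks$body_ref$mask], 0.9))
    if (length(cand) < spec$n_landmarks)
      stop(sprintf("only %d high-gradient voxels available for %d landmarks",
                   length(cand), spec$n_landmarks))
    pick <- sort(sample(cand, spec$n_landmarks))
    av <- arrayInd(pick, d) - 1  # 0-based (z,y,x)
    disp_at <- vapply(1:3, function(k) field$disp[, , , k][pick],
                      numeric(length(pick)))
    ref_mm <- voxel_to_world(geom, av)
    flt_mm <- voxel_to_world(geom, av + disp_at)
    lm <- landmark_set(data.frame(
      label = sprintf("L%03d", seq_len(spec$n_landmarks)),
      ref_z = ref_mm[, 1], ref_y = ref_mm[, 2], ref_x = ref_mm[, 3],
      flt_z = flt_mm[, 1], flt_y = flt_mm[, 2], flt_x = flt_mm[, 3]))

    # EBRT dose, floating frame: a wide, nearly uniform in-field plateau
    # plus a smooth offset boost that gives the distribution internal
    # gradients away from the applicator
    pl <- exp(-(((co$Z - cen[1]) / 100)^8 + ((co$Y - cen[2]) / 80)^8 +
                  ((co$X - cen[3]) / 85)^8))
    bo <- spec$ebrt_boost
    bc <- cen + bo$center_offset_mm
    boost <- bo$amp_gy * exp(-((co$Z - bc[1])^2 + (co$Y - bc[2])^2 +
                                 (co$X - bc[3])^2) / (2 * bo$sigma_mm^2))
    ebrt <- dose_grid(spec$ebrt_plateau_gy * pl + boost * pl, spec$spacing)

    # BRT dose: capped inverse-square falloff around source points on the
    # rods, reference frame (steep gradient near the applicator)
    src <- if (ap$n_rods > 0)
      do.call(rbind, lapply(ap$x_offsets_mm[seq_len(ap$n_rods)], function(xo)
        cbind(cen[1] + c(-10, 0, 10), cen[2], cen[3] + xo)))
      else matrix(numeric(0), 0, 3)
    brt <- array(0, d)
    for (i in seq_len(nrow(src))) {
      r2 <- (co$Z - src[i, 1])^2 + (co$Y - src[i, 2])^2 + (co$X - src[i, 3])^2
      brt <- brt + (spec$brt_d10_gy / nrow(src)) * 100 / (r2 + 1)
    }
    brt <- dose_grid(pmin(brt, spec$brt_cap_gy), spec$spacing)

    list(bundle = case_bundle(
           reference_ct = ref_ct, floating_ct = flt_ct,
           reference_dose = brt, floating_dose = ebrt,
           masks = masks, landmarks = lm,
           fractionation = list(
             ebrt = fractionation_scheme(25, 10, 45),
             brt = fractionation_scheme(4, 10, 28))),
         field = field, spec = spec)
  })
}

#' Smooth validation phantom
#'
#' A dedicated fixture for motion-capture and affine-recovery checks: a
#' global intensity ramp (so the gradient never vanishes and the
#' least-squares system is well conditioned everywhere), broad Gaussian
#' blobs carrying large-scale structure that survives downsampling, and a
#' fine blob band whose features decorrelate under multi-voxel motion.
#' Together these expose the coarse-to-fine behavior of the registration:
#' a single-scale run locks onto wrong fine-texture correspondences under
#' large translations, while the pyramid first captures the bulk motion on
#' the smooth content and then refines on the fine texture.
#'
#' @param shape grid size `(nz, ny, nx)`.
#' @param spacing voxel size in mm.
#' @param seed RNG seed; fixed seed gives identical volumes.
#' @return An [image_volume()].
#' @export
make_smooth_phantom <- function(shape = c(24L, 72L, 72L),
                                spacing = c(2.5, 1, 1), seed = 1L) {
  d <- as.integer(shape)
  iz <- array(seq_len(d[1]) - 1, d)
  iy <- array(rep(seq_len(d[2]) - 1, each = d[1]), d)
  ix <- array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), d)
  # blob-center margins shrink proportionally on small grids
  lo <- pmin(c(4, 10, 10), 0.3 * d)
  hi <- pmax(d - c(4, 10, 10), 0.7 * d)
  lo_f <- pmin(c(2, 4, 4), 0.3 * d)
  hi_f <- pmax(d - c(2, 4, 4), 0.7 * d)
  with_local_seed(seed, {
    broad <- array(0, d); fine <- array(0, d)
    for (i in 1:30) {
      c0 <- stats::runif(3, lo, hi)
      s <- stats::runif(1, 15, 25); a <- stats::runif(1, -120, 120)
      broad <- broad + a * exp(-((iz - c0[1])^2 + (iy - c0[2])^2 +
                                   (ix - c0[3])^2) / (2 * s^2))
    }
    for (i in 1:250) {
      c0 <- stats::runif(3, lo_f, hi_f)
      s <- stats::runif(1, 1.6, 2.2); a <- stats::runif(1, -70, 70)
      fine <- fine + a * exp(-((iz - c0[1])^2 + (iy - c0[2])^2 +
                                 (ix - c0[3])^2) / (2 * s^2))
    }
    image_volume(5 * iz + 7 * iy + 9 * ix + broad + fine, spacing)
  })
}
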