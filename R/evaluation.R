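# Registration accuracy metrics (landmark distance, masked HU RMSE, 2D
# gamma analysis) and DVH hot-spot extraction with the DVH-addition vs
# DIR-accumulation comparison.

#' Gamma analysis parameters
#'
#' Defaults follow the 2%/2 mm local-reference criterion. The search is an
#' exhaustive minimum over a polar-sorted offset grid of pitch
#' `search_step_mm` out to `search_radius_mm`, with evaluated values
#' bilinearly interpolated.
#'
#' @param dose_crit_pct value-difference criterion in percent.
#' @param dist_crit_mm distance-to-agreement criterion in mm.
#' @param mode `"local"` (criterion scales with the reference value) or
#'   `"global"` (criterion scales with the masked reference range).
#' @param search_radius_mm search disc radius; at least `dist_crit_mm`.
#' @param search_step_mm search grid pitch; at most `dist_crit_mm / 4`.
#' @param low_cut reference pixels with `|value|` below this are skipped.
#' @param local_floor floor on `|reference|` in the local denominator,
#'   guarding against division by zero near 0 HU.
#' @return A `gamma_params` list.
#' @export
gamma_params <- function(dose_crit_pct = 2, dist_crit_mm = 2,
                         mode = c("local", "global"),
                         search_radius_mm = 3 * dist_crit_mm,
                         search_step_mm = dist_crit_mm / 10,
                         low_cut = 0, local_floor = 1) {
  mode <- match.arg(mode)
  stopifnot(dose_crit_pct > 0, dist_crit_mm > 0,
            search_radius_mm >= dist_crit_mm,
            search_step_mm <= dist_crit_mm / 4)
  structure(list(dose_crit_pct = dose_crit_pct, dist_crit_mm = dist_crit_mm,
                 mode = mode, search_radius_mm = search_radius_mm,
                 search_step_mm = search_step_mm, low_cut = low_cut,
                 local_floor = local_floor),
            class = "gamma_params")
}

#' Landmark distance before / after registration
#'
#' Without a field, the plain Euclidean world-mm distance between paired
#' points. With a field (and optionally the preregistration transform), the
#' reference point is mapped through the model -- `x + disp(x)` in voxels,
#' back to mm, then through `transform` -- and the residual to the
#' annotated floating point is reported.
#'
#' @param landmarks a [landmark_set()].
#' @param field optional [deformation_field()] on the reference geometry.
#' @param transform optional [affine_transform()] applied after the field
#'   (the preregistration step), mapping registered-frame points into the
#'   original floating frame.
#' @return List with `per_point` distances (mm), `mean`, `min`, `max`.
#' @export
landmark_distance <- function(landmarks, field = NULL, transform = NULL) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (nrow(landmarks) == 0L) stop("empty landmark set")
  refp <- lm_ref_points(landmarks)
  fltp <- lm_flt_points(landmarks)
  pred <- refp
  if (!is.null(field)) {
    geom <- geometry_of(field)
    v <- world_to_voxel(geom, refp)
    disp <- vapply(1:3, function(k)
      cpp_trilinear(as.numeric(field$disp[, , , k]), geom$dim, v), numeric(nrow(v)))
    pred <- voxel_to_world(geom, v + disp)
  }
  if (!is.null(transform)) pred <- affine_apply_points(transform, pred)
  d <- sqrt(rowSums((pred - fltp)^2))
  list(per_point = d, mean = mean(d), min = min(d), max = max(d))
}

#' Root-mean-square HU error within a mask
#'
#' @param ref,registered `image_volume`s on the same geometry.
#' @param body_mask a non-empty [structure_mask()] (the patient contour;
#'   couch and air differences are excluded).
#' @return RMSE in HU.
#' @export
rmse_within_mask <- function(ref, registered, body_mask) {
  if (!same_geometry(ref, registered))
    stop_geometry_mismatch(ref, registered, "reference and registered")
  if (!same_geometry(ref, body_mask))
    stop_geometry_mismatch(ref, body_mask, "reference and mask")
  if (body_mask$empty) stop("body mask is empty")
  d <- ref$data[body_mask$mask] - registered$data[body_mask$mask]
  sqrt(mean(d^2))
}

#' 2D gamma analysis of one axial slice
#'
#' For every reference pixel inside the mask, the gamma index is the
#' minimum over nearby evaluated positions `e` of
#' `sqrt((|e-r| / dist_crit)^2 + ((V_eval(e) - V_ref(r)) / crit_V)^2)`,
#' with `crit_V` the local (percent of `|V_ref(r)|`) or global criterion.
#' A pixel passes when gamma <= 1. Here the compared values are HU: the CT
#' slices are pushed through the dose-comparison formalism unchanged.
#'
#' @param ref_slice,eval_slice numeric `ny x nx` matrices (HU).
#' @param mask_slice logical `ny x nx` matrix of evaluated pixels.
#' @param spacing_yx in-plane pixel spacing `(sy, sx)` in mm.
#' @param params a [gamma_params()].
#' @return List with `gamma_map` (NA outside the mask), `pass_rate_pct`
#'   and `n_evaluated`.
#' @export
gamma_slice <- function(ref_slice, eval_slice, mask_slice, spacing_yx,
                        params = gamma_params()) {
  stopifnot(all(dim(ref_slice) == dim(eval_slice)),
            all(dim(ref_slice) == dim(mask_slice)))
  global_denom <- if (params$mode == "global") {
    rng <- diff(range(ref_slice[mask_slice]))
    params$dose_crit_pct / 100 * max(rng, params$local_floor)
  } else 0
  gmap <- cpp_gamma_slice(ref_slice, eval_slice, mask_slice,
                          spacing_yx[1], spacing_yx[2],
                          params$dist_crit_mm, params$dose_crit_pct / 100,
                          params$mode == "local", global_denom,
                          params$search_radius_mm, params$search_step_mm,
                          params$low_cut, params$local_floor)
  ev <- !is.na(gmap)
  n <- sum(ev)
  list(gamma_map = gmap,
       pass_rate_pct = if (n) 100 * sum(gmap[ev] <= 1) / n else NA_real_,
       n_evaluated = n)
}

#' Study-level gamma score
#'
#' Runs [gamma_slice()] on every axial slice within the body contour and
#' averages the per-slice pass rates over the evaluable slices (slices with
#' no evaluated pixel are flagged and excluded).
#'
#' @param ref,registered `image_volume`s on the same geometry.
#' @param body_mask a [structure_mask()].
#' @param params a [gamma_params()].
#' @return List with `study_pct` (mean over slices), `per_slice` data frame
#'   (`slice, pass_rate_pct, n_evaluated`).
#' @export
gamma_study <- function(ref, registered, body_mask, params = gamma_params()) {
  if (!same_geometry(ref, registered))
    stop_geometry_mismatch(ref, registered, "reference and registered")
  if (!same_geometry(ref, body_mask))
    stop_geometry_mismatch(ref, body_mask, "reference and mask")
  nz <- dim(ref$data)[1]
  rates <- numeric(nz); nev <- integer(nz)
  for (i in seq_len(nz)) {
    gs <- gamma_slice(ref$data[i, , ], registered$data[i, , ],
                      body_mask$mask[i, , ], ref$spacing[2:3], params)
    rates[i] <- gs$pass_rate_pct
    nev[i] <- gs$n_evaluated
  }
  ok <- nev > 0
  if (!any(ok)) stop("no evaluable slice (empty body mask?)")
  list(study_pct = mean(rates[ok]),
       per_slice = data.frame(slice = seq_len(nz), pass_rate_pct = rates,
                              n_evaluated = nev))
}

#' Cumulative dose-volume histogram
#'
#' @param dose a [dose_grid()].
#' @param mask a non-empty [structure_mask()] on the dose geometry.
#' @param bin_gy histogram bin width in Gy.
#' @return A `dvh` object: data frame with `dose_gy` (bin lower edge) and
#'   `volume_frac` (fraction of the structure receiving at least that dose),
#'   with the voxel volume in cm^3 as an attribute.
#' @export
dvh <- function(dose, mask, bin_gy = 0.01) {
  if (!same_geometry(dose, mask)) stop_geometry_mismatch(dose, mask, "dose and mask")
  if (mask$empty) stop("mask is empty")
  d <- dose$data[mask$mask]
  vox_cm3 <- prod(dose$spacing) / 1000
  bins <- seq(0, max(d) + bin_gy, by = bin_gy)
  # fraction of voxels with dose >= bin edge
  frac <- 1 - (findInterval(bins, sort(d), left.open = TRUE)) / length(d)
  out <- data.frame(dose_gy = bins, volume_frac = frac)
  attr(out, "voxel_cm3") <- vox_cm3
  attr(out, "structure") <- mask$name
  class(out) <- c("dvh", "data.frame")
  out
}

#' Minimum dose to the hottest v cm^3 of a structure
#'
#' The exact sorted-voxel estimator: voxel doses inside the mask are sorted
#' descending and D_v is the k-th value with
#' `k = ceiling(v_cm3 / voxel_volume_cm3)` -- the minimum EQD2 received by
#' the hottest `v` cm^3 (the GEC-ESTRO D_0.1cm3 / D_2cm3 parameters).
#'
#' @param dose a [dose_grid()].
#' @param mask a non-empty [structure_mask()] on the dose geometry.
#' @param v_cm3 volume in cm^3, at most the structure volume.
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dose, mask, v_cm3) {
  if (!same_geometry(dose, mask)) stop_geometry_mismatch(dose, mask, "dose and mask")
  if (mask$empty) stop("mask is empty")
  vox_cm3 <- prod(dose$spacing) / 1000
  nvox <- sum(mask$mask)
  vol_cm3 <- nvox * vox_cm3
  if (v_cm3 > vol_cm3)
    stop(sprintf("requested volume %.3f cm^3 exceeds structure volume %.3f cm^3",
                 v_cm3, vol_cm3))
  k <- ceiling(v_cm3 / vox_cm3)
  k <- max(1L, min(k, nvox))
  sort(dose$data[mask$mask], decreasing = TRUE)[k]
}

#' DVH-parameter addition vs DIR-based accumulation
#'
#' Compares the clinical standard -- adding the D_v parameters of the two
#' course DVHs after EQD2 conversion -- with the D_v of the deformably
#' mapped and accumulated distribution. Because the hottest sub-volumes of
#' the two courses rarely coincide anatomically, simple addition
#' systematically overestimates the accumulated hot-spot dose.
#'
#' @param ebrt_eqd2 EBRT-course EQD2 `dose_grid` (floating frame).
#' @param brt_eqd2 BRT-course EQD2 `dose_grid` (reference frame).
#' @param field a [deformation_field()] on the reference geometry.
#' @param mask organ mask in the reference frame.
#' @param v_cm3 volumes to evaluate (cm^3).
#' @param mask_floating optional organ mask in the floating frame for the
#'   EBRT D_v; defaults to `mask` (appropriate when both frames share the
#'   geometry and the organ barely moves, as for additive comparisons).
#' @return Data frame with one row per volume: `v_cm3`, `added_gy`,
#'   `dir_gy`, `diff_gy` (added - dir) and `diff_pct_of_dir`.
#' @export
compare_accumulation <- function(ebrt_eqd2, brt_eqd2, field, mask,
                                 v_cm3 = c(0.1, 2), mask_floating = NULL) {
  if (is.null(mask_floating)) mask_floating <- mask
  mapped <- map_dose(resample_to_geometry(ebrt_eqd2, field), field)
  accum <- accumulate_dose(mapped, brt_eqd2)
  rows <- lapply(v_cm3, function(v) {
    added <- dose_at_volume(ebrt_eqd2, mask_floating, v) +
      dose_at_volume(brt_eqd2, mask, v)
    dir <- dose_at_volume(accum, mask, v)
    data.frame(v_cm3 = v, added_gy = added, dir_gy = dir,
               diff_gy = added - dir,
               diff_pct_of_dir = (added - dir) / dir * 100)
  })
  do.call(rbind, rows)
}
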