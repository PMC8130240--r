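# Applicator removal: the brachytherapy applicator exists only in the
# reference CT, so before registration its voxels are replaced by random HU
# drawn around the mean of the surrounding tissue and the replaced region is
# Gaussian-blurred.

#' In-painting parameters
#'
#' @param hu_halfwidth half-width of the uniform HU draw around the
#'   surrounding-tissue mean, in HU (default 200, i.e. mean +/- 200 HU).
#' @param ring_width_voxels width of the dilation ring defining the
#'   "surrounding tissue" whose mean HU seeds the draw.
#' @param blur_sigma_mm Gaussian blur width applied to the replaced region.
#' @param seed integer RNG seed for the HU draw.
#' @return An `inpaint_params` list.
#' @export
inpaint_params <- function(hu_halfwidth = 200, ring_width_voxels = 2L,
                           blur_sigma_mm = 1.5, seed = 1L) {
  stopifnot(hu_halfwidth >= 0, ring_width_voxels >= 1, blur_sigma_mm >= 0)
  structure(list(hu_halfwidth = hu_halfwidth,
                 ring_width_voxels = as.integer(ring_width_voxels),
                 blur_sigma_mm = blur_sigma_mm, seed = as.integer(seed)),
            class = "inpaint_params")
}

ball_offsets <- function(r) {
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2 + 1e-9, , drop = FALSE]
}

#' Binary dilation of a structure mask
#'
#' Dilation with a Euclidean ball of radius `r_voxels` in voxel units
#' (for radius 1 this is the 7-voxel face-connected cross).
#'
#' @param mask a [structure_mask()].
#' @param r_voxels integer radius `>= 1`.
#' @return The dilated `structure_mask`.
#' @export
dilate_mask <- function(mask, r_voxels) {
  stopifnot(inherits(mask, "structure_mask"), r_voxels >= 1)
  d <- dim(mask$mask)
  out <- array(FALSE, d)
  idx <- which(mask$mask, arr.ind = TRUE)
  if (nrow(idx)) {
    offs <- ball_offsets(as.integer(r_voxels))
    for (i in seq_len(nrow(offs))) {
      z <- idx[, 1] + offs$dz[i]; y <- idx[, 2] + offs$dy[i]; x <- idx[, 3] + offs$dx[i]
      ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
      out[cbind(z[ok], y[ok], x[ok])] <- TRUE
    }
  }
  structure_mask(mask$name, out, mask$spacing, mask$origin)
}

#' Replace the applicator with randomized tissue-like HU
#'
#' Every masked voxel is set to an independent uniform draw from
#' `mean(ring) +/- hu_halfwidth` HU, where the ring is the surrounding
#' tissue (a morphological dilation of the mask minus the mask). The
#' replaced region is then Gaussian-blurred; the blurred values are written
#' back only inside a one-voxel dilation of the mask, so everything outside
#' that region is bit-identical to the input.
#'
#' @param ct an [image_volume()] (the reference / BRT-frame CT).
#' @param applicator_mask a [structure_mask()] on the CT geometry.
#' @param params an [inpaint_params()].
#' @return The in-painted `image_volume`.
#' @export
replace_applicator <- function(ct, applicator_mask,
                               params = inpaint_params()) {
  stopifnot(inherits(ct, "image_volume"))
  if (!same_geometry(ct, applicator_mask))
    stop_geometry_mismatch(ct, applicator_mask, "CT and applicator mask")
  if (applicator_mask$empty) stop("applicator mask is empty")
  ring_mask <- dilate_mask(applicator_mask, params$ring_width_voxels)
  ring <- ring_mask$mask & !applicator_mask$mask
  if (!any(ring))
    stop("surrounding-tissue ring is empty (mask fills the whole volume?)")
  m <- mean(ct$data[ring])
  n <- sum(applicator_mask$mask)
  filled <- ct$data
  filled[applicator_mask$mask] <- with_local_seed(params$seed,
    stats::runif(n, m - params$hu_halfwidth, m + params$hu_halfwidth))
  region <- dilate_mask(applicator_mask, 1L)$mask
  if (params$blur_sigma_mm > 0) {
    blurred <- blur_array(filled, params$blur_sigma_mm / ct$spacing)
    filled[region] <- blurred[region]
  }
  out <- ct
  out$data <- filled
  out
}
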