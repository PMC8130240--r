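# Interpolation, warping and resampling shared by every module.

#' Trilinear interpolation in a volume
#'
#' Samples a scalar volume at continuous 0-based voxel coordinates with
#' trilinear interpolation of the eight surrounding voxels. Coordinates
#' outside the grid are clamped to the edge, so the result always lies
#' within the range of the stored values.
#'
#' @param vol an `image_volume` or `dose_grid`.
#' @param p numeric vector of 3 `(z, y, x)` voxel coordinates, or an
#'   `n x 3` matrix of them.
#' @return Scalar (or length-n vector) of interpolated values.
#' @export
trilinear_sample <- function(vol, p) {
  if (!is.matrix(p)) p <- matrix(p, ncol = 3)
  if (ncol(p) != 3L) stop("p must have 3 components (z, y, x)")
  if (any(!is.finite(p))) stop("invalid coordinate: non-finite components")
  cpp_trilinear(as.numeric(vol$data), dim(vol$data), p)
}

#' Warp a volume through a deformation field
#'
#' Backward (pull) warping: output voxel `x` takes the trilinearly
#' interpolated input value at `x + disp(x)`. The output lives on the
#' field's reference geometry. Out-of-grid reads are edge-clamped.
#'
#' @param vol an `image_volume` or `dose_grid` aligned with the field's
#'   reference geometry.
#' @param field a [deformation_field()].
#' @return Warped object of the same class as `vol`.
#' @export
warp_volume <- function(vol, field) {
  if (!same_geometry(vol, field))
    stop_geometry_mismatch(vol, field, "volume and deformation field")
  d <- geometry_of(field)$dim
  w <- cpp_warp(as.numeric(vol$data), d,
                as.numeric(field$disp[, , , 1]),
                as.numeric(field$disp[, , , 2]),
                as.numeric(field$disp[, , , 3]))
  out <- vol
  out$data <- array(w, d)
  out
}

#' Compose a field update into a base field
#'
#' Residual-flow composition used by the coarse-to-fine scheme:
#' `disp_out(x) = update(x) + disp_base(x + update(x))`, the base field
#' being sampled trilinearly at the updated position. This is a true
#' composition of the two warps, not a plain addition.
#'
#' @param base,update `deformation_field`s on the same geometry.
#' @return The composed `deformation_field`.
#' @export
compose_update <- function(base, update) {
  if (!same_geometry(base, update))
    stop_geometry_mismatch(base, update, "base and update fields")
  d <- geometry_of(base)$dim
  uz <- as.numeric(update$disp[, , , 1])
  uy <- as.numeric(update$disp[, , , 2])
  ux <- as.numeric(update$disp[, , , 3])
  out <- update
  for (k in 1:3) {
    bk <- cpp_warp(as.numeric(base$disp[, , , k]), d, uz, uy, ux)
    out$disp[, , , k] <- out$disp[, , , k] + array(bk, d)
  }
  out
}

#' Resample a volume onto another geometry
#'
#' Trilinear resampling through world coordinates; used e.g. to bring an
#' RTDOSE grid onto the CT grid. Out-of-field voxels are edge-clamped.
#'
#' @param vol an `image_volume` or `dose_grid`.
#' @param geom target [grid_geometry()] (or object carrying one).
#' @return `vol` resampled onto `geom`.
#' @export
resample_to_geometry <- function(vol, geom) {
  geom <- geometry_of(geom)
  if (same_geometry(vol, geom)) return(vol)
  A <- diag(3)
  w <- cpp_affine_resample(as.numeric(vol$data), dim(vol$data),
                           vol$spacing, vol$origin,
                           geom$dim, geom$spacing, geom$origin,
                           A, c(0, 0, 0))
  out <- vol
  out$data <- array(w, geom$dim)
  out$spacing <- geom$spacing
  out$origin <- geom$origin
  out
}

# truncated Gaussian kernel, radius r voxels; unnormalized weights
gauss_kernel <- function(sigma, r) {
  if (r < 1) return(1)
  t <- (-r):r
  exp(-t^2 / (2 * sigma^2))
}

# renormalized Gaussian blur; sigma per axis in voxel units (0 = no blur)
blur_array <- function(arr, sigma_vox) {
  d <- dim(arr)
  ks <- lapply(1:3, function(a) {
    s <- sigma_vox[a]
    if (s <= 0) return(1)
    k <- gauss_kernel(s, max(1L, ceiling(3 * s)))
    k / sum(k)
  })
  num <- cpp_sepconv(as.numeric(arr), d, ks[[1]], ks[[2]], ks[[3]])
  den <- cpp_sepconv(rep(1, length(arr)), d, ks[[1]], ks[[2]], ks[[3]])
  array(num / den, d)
}

#' Gaussian blur of a volume
#'
#' Separable Gaussian smoothing with the kernel renormalized at the borders
#' (a convex combination of in-grid values, so no new extrema appear).
#'
#' @param vol an `image_volume` or `dose_grid`.
#' @param sigma_mm Gaussian width in mm (scalar, isotropic in world units).
#' @return Blurred volume of the same class and geometry.
#' @export
gaussian_blur <- function(vol, sigma_mm) {
  if (sigma_mm < 0) stop("sigma_mm must be >= 0")
  if (sigma_mm == 0) return(vol)
  out <- vol
  out$data <- blur_array(vol$data, sigma_mm / vol$spacing)
  out
}
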