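# Weighted-window Lucas-Kanade optical flow in 3D, wrapped in a
# coarse-to-fine image pyramid with iterative residual refinement.
#
# At every voxel the flow v solves the weighted normal equations
#     (sum_w w g g^T) v = -(sum_w w g g_t)
# over a (2r+1)^3 window, with Gaussian-of-distance weights. The Gaussian
# weight factorizes per axis, so all nine window sums are exact separable
# convolutions of the gradient-product images.

#' Lucas-Kanade registration parameters
#'
#' The two parameters that matter most are the pyramid depth and the
#' neighborhood radius; two levels with radius 3 (a 7x7x7 window) is the
#' optimized default. `weight_sigma` controls how quickly window weights
#' decay with distance from the center voxel.
#'
#' @param pyramid_levels number of pyramid levels (1 = single scale).
#' @param window_radius neighborhood radius `r` in voxels; window size
#'   `(2r+1)^3`.
#' @param weight_sigma Gaussian weight width in voxels. The default `2r/3`
#'   leaves the window edge with weight `exp(-9/8)` (about a third of the
#'   center), so the whole window stays informative while closer voxels
#'   still dominate; much narrower weights shrink the effective window and
#'   with it the per-level motion capture range.
#' @param iters_per_level warp-and-solve iteration budget per level,
#'   finest level first (a scalar applies everywhere; a shorter vector is
#'   extended with its last value for coarser levels). The default
#'   `c(3, 10)` gives the coarse, high-SNR levels the capture budget while
#'   keeping full-resolution refinement short: without field
#'   regularization, further full-resolution iterations accumulate
#'   intensity-noise-driven flow noise instead of accuracy. Iteration also
#'   stops early once the mean update norm falls below
#'   `stop_mean_update`.
#' @param min_eigen_factor smallest-eigenvalue gate for the normal matrix,
#'   as a fraction of the window weight mass: voxels whose smallest
#'   eigenvalue falls below `min_eigen_factor * sum(weights)` get a zero
#'   update (the aperture-problem / homogeneous-tissue guard).
#' @param update_clip per-iteration cap on each displacement component,
#'   in voxels (`Inf` disables).
#' @param stop_mean_update early-stop threshold on the mean update norm.
#' @return An `lk_params` list.
#' @export
lk_params <- function(pyramid_levels = 2L, window_radius = 3L,
                      weight_sigma = 2 * window_radius / 3,
                      iters_per_level = c(3L, 10L), min_eigen_factor = 1e-4,
                      update_clip = 1.5, stop_mean_update = 0.01) {
  stopifnot(pyramid_levels >= 1, window_radius >= 1, weight_sigma > 0,
            all(iters_per_level >= 1), min_eigen_factor >= 0)
  structure(list(pyramid_levels = as.integer(pyramid_levels),
                 window_radius = as.integer(window_radius),
                 weight_sigma = weight_sigma,
                 iters_per_level = as.integer(iters_per_level),
                 min_eigen_factor = min_eigen_factor,
                 update_clip = update_clip,
                 stop_mean_update = stop_mean_update),
            class = "lk_params")
}

#' Spatial intensity gradients
#'
#' Central differences on the interior, one-sided at borders, in HU per
#' voxel along each axis.
#'
#' @param vol an `image_volume` (or any scalar volume).
#' @return List with 3D arrays `gz`, `gy`, `gx`.
#' @export
spatial_gradients <- function(vol) {
  d <- dim(vol$data)
  if (any(d < 2)) stop("every axis must have length >= 2 for gradients")
  g <- cpp_gradients(as.numeric(vol$data), d)
  list(gz = array(g$gz, d), gy = array(g$gy, d), gx = array(g$gx, d))
}

#' Build a coarse-to-fine image pyramid
#'
#' Level 1 is the input; each following level is Gaussian-smoothed
#' (sigma 1 voxel) and 2x downsampled in-plane. The slice axis joins the
#' downsampling only while at least 8 slices remain (axial slices are
#' already coarse). Spacing metadata doubles accordingly.
#'
#' @param vol an `image_volume` or `dose_grid`.
#' @param levels number of levels `>= 1`.
#' @return List of volumes, finest first.
#' @export
build_pyramid <- function(vol, levels) {
  stopifnot(levels >= 1)
  out <- vector("list", levels)
  out[[1]] <- vol
  cur <- vol
  for (k in seq_len(levels - 1)) {
    d <- dim(cur$data)
    if (any(d[2:3] < 8))
      stop(sprintf("volume too small for %d pyramid levels (in-plane %dx%d at level %d)",
                   levels, d[2], d[3], k))
    down_z <- d[1] >= 8
    sig <- c(if (down_z) 1 else 0, 1, 1)
    sm <- blur_array(cur$data, sig)
    zi <- if (down_z) seq(1, d[1], by = 2) else seq_len(d[1])
    yi <- seq(1, d[2], by = 2)
    xi <- seq(1, d[3], by = 2)
    nxt <- cur
    nxt$data <- sm[zi, yi, xi, drop = FALSE]
    nxt$spacing <- cur$spacing * c(if (down_z) 2 else 1, 2, 2)
    # voxel 0 keeps its world position
    cur <- nxt
    out[[k + 1]] <- cur
  }
  out
}

#' Lucas-Kanade flow at a single scale
#'
#' Iterates: warp the floating image through the current field, compute the
#' temporal difference and spatial gradients of the warped image, solve the
#' weighted 3x3 normal system at every voxel over the `(2r+1)^3` window,
#' gate degenerate systems by their smallest eigenvalue, clip the update,
#' and compose it into the field. Fully deterministic.
#'
#' @param ref,flt `image_volume`s on the same geometry.
#' @param params an [lk_params()] (its `pyramid_levels` is ignored here).
#' @param init_field optional initial [deformation_field()]; zero if `NULL`.
#' @return The refined `deformation_field`.
#' @export
lk_flow_level <- function(ref, flt, params = lk_params(), init_field = NULL) {
  if (!same_geometry(ref, flt))
    stop_geometry_mismatch(ref, flt, "reference and floating")
  geom <- geometry_of(ref)
  field <- if (is.null(init_field)) zero_field(geom) else init_field
  if (!same_geometry(field, ref))
    stop_geometry_mismatch(field, ref, "init field and reference")
  r <- params$window_radius
  k1 <- gauss_kernel(params$weight_sigma, r)
  wmass <- sum(k1)^3
  eig_thresh <- params$min_eigen_factor * wmass
  d <- geom$dim
  refv <- as.numeric(ref$data)
  conv <- function(a) cpp_sepconv(a, d, k1, k1, k1)
  for (it in seq_len(params$iters_per_level[1])) {
    warped <- cpp_warp(as.numeric(flt$data), d,
                       as.numeric(field$disp[, , , 1]),
                       as.numeric(field$disp[, , , 2]),
                       as.numeric(field$disp[, , , 3]))
    g <- cpp_gradients(warped, d)
    gt <- warped - refv
    sol <- cpp_lk_solve(conv(g$gz * g$gz), conv(g$gz * g$gy), conv(g$gz * g$gx),
                        conv(g$gy * g$gy), conv(g$gy * g$gx), conv(g$gx * g$gx),
                        conv(g$gz * gt), conv(g$gy * gt), conv(g$gx * gt),
                        eig_thresh, params$update_clip)
    upd <- field
    upd$disp <- array(c(sol$vz, sol$vy, sol$vx), c(d, 3L))
    field <- compose_update(field, upd)
    mean_upd <- mean(sqrt(sol$vz^2 + sol$vy^2 + sol$vx^2))
    if (mean_upd < params$stop_mean_update) break
  }
  field
}

# resample a field defined on `from` geometry onto `to` geometry, scaling
# displacement components by the per-axis resolution ratio
upsample_field <- function(field, to_geom) {
  from <- geometry_of(field)
  to_geom <- geometry_of(to_geom)
  ratio <- from$spacing / to_geom$spacing  # coarse voxel -> fine voxels
  A <- diag(3)
  comps <- lapply(1:3, function(k) {
    w <- cpp_affine_resample(as.numeric(field$disp[, , , k]), from$dim,
                             from$spacing, from$origin,
                             to_geom$dim, to_geom$spacing, to_geom$origin,
                             A, c(0, 0, 0))
    w * ratio[k]
  })
  deformation_field(array(unlist(comps), c(to_geom$dim, 3L)),
                    to_geom$spacing, to_geom$origin)
}

#' Pyramidal Lucas-Kanade deformable registration
#'
#' Registers at the coarsest pyramid level first, then propagates the field
#' to each finer level as the initial estimate and solves for the residual
#' flow, which lets the method capture deformations far larger than the
#' window while keeping the small-motion assumption valid at each level.
#' No post-optimization regularization of the field is applied; use
#' [jacobian_report()] to diagnose folding instead.
#'
#' @param ref,flt `image_volume`s on the same geometry (after any rigid
#'   preregistration).
#' @param params an [lk_params()].
#' @param init_field optional full-resolution initial
#'   [deformation_field()], e.g. the affine stage's `affine_to_field()`
#'   output; it is downsampled to the coarsest level and refined from
#'   there, so the floating image is never resampled twice.
#' @return The full-resolution [deformation_field()].
#' @export
pyramid_lk_register <- function(ref, flt, params = lk_params(),
                                init_field = NULL) {
  if (!same_geometry(ref, flt))
    stop_geometry_mismatch(ref, flt, "reference and floating")
  ref_pyr <- build_pyramid(ref, params$pyramid_levels)
  flt_pyr <- build_pyramid(flt, params$pyramid_levels)
  field <- if (is.null(init_field)) NULL
           else upsample_field(init_field, ref_pyr[[params$pyramid_levels]])
  iters <- params$iters_per_level
  for (lev in seq(params$pyramid_levels, 1)) {
    if (!is.null(field)) field <- upsample_field(field, ref_pyr[[lev]])
    plev <- params
    plev$iters_per_level <- iters[min(lev, length(iters))]
    field <- lk_flow_level(ref_pyr[[lev]], flt_pyr[[lev]], plev, field)
  }
  field
}

#' Diagnose non-diffeomorphic (folding) regions of a field
#'
#' Computes the finite-difference Jacobian determinant of the mapping
#' `x + disp(x)` at every interior voxel and reports the fraction that is
#' non-positive. The registration itself never smooths or fixes the field.
#'
#' @param field a [deformation_field()].
#' @return List with `n_negative`, `fraction_negative` and `min_jacobian`.
#' @export
jacobian_report <- function(field) {
  d <- dim(field$disp)[1:3]
  J <- array(1, d)
  dd <- field$disp
  ctr <- function(a, axis) {
    # central difference along axis, interior only
    n <- dim(a)[axis]
    idx_p <- 3:n; idx_m <- 1:(n - 2)
    out <- array(0, dim(a))
    if (axis == 1) out[2:(n - 1), , ] <- (a[idx_p, , ] - a[idx_m, , ]) / 2
    if (axis == 2) out[, 2:(n - 1), ] <- (a[, idx_p, ] - a[, idx_m, ]) / 2
    if (axis == 3) out[, , 2:(n - 1)] <- (a[, , idx_p] - a[, , idx_m]) / 2
    out
  }
  g <- array(0, c(d, 3, 3))
  for (k in 1:3) for (a in 1:3) {
    g[, , , k, a] <- ctr(dd[, , , k], a) + (k == a)
  }
  J <- g[, , , 1, 1] * (g[, , , 2, 2] * g[, , , 3, 3] - g[, , , 2, 3] * g[, , , 3, 2]) -
       g[, , , 1, 2] * (g[, , , 2, 1] * g[, , , 3, 3] - g[, , , 2, 3] * g[, , , 3, 1]) +
       g[, , , 1, 3] * (g[, , , 2, 1] * g[, , , 3, 2] - g[, , , 2, 2] * g[, , , 3, 1])
  Ji <- J[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  list(n_negative = sum(Ji <= 0),
       fraction_negative = mean(Ji <= 0),
       min_jacobian = min(Ji))
}
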