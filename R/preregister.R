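# Rigid and affine preregistration of the floating (EBRT) CT to the
# reference (BRT) CT. The affine stage minimizes the masked mean-squared HU
# difference over the overlap domain by multi-resolution quasi-Newton
# optimization of the 12 affine parameters; the rigid stage applies
# user-supplied bone-match parameters.

#' Affine transform in world coordinates
#'
#' Maps a point `p` in the reference world frame to the corresponding point
#' `q = M p + b` in the floating world frame (the backward-resampling
#' direction: a volume is registered by reading, for each reference voxel,
#' the floating intensity at `q`). Components are in `(z, y, x)` order.
#'
#' @param matrix invertible 3x3 matrix.
#' @param translation length-3 translation in mm.
#' @return An `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  if (abs(det(matrix)) <= 1e-8) stop("affine matrix is singular")
  structure(list(matrix = matrix, translation = as.numeric(translation)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> q = M p + b (z,y,x world mm)\nM =\n")
  print(round(x$matrix, 6))
  cat("b =", paste(format(round(x$translation, 4)), collapse = ", "), "mm\n")
  invisible(x)
}

#' Invert an affine transform
#' @param t an [affine_transform()].
#' @return The inverse `affine_transform`.
#' @export
affine_invert <- function(t) {
  Mi <- solve(t$matrix)
  affine_transform(Mi, -Mi %*% t$translation)
}

affine_apply_points <- function(t, p) {
  # p: n x 3 matrix (z,y,x world mm)
  sweep(p %*% t(t$matrix), 2, t$translation, "+")
}

# rotation matrices acting on (z,y,x)-ordered world vectors
rot3 <- function(axis, deg) {
  th <- deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  switch(axis,
    z = matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, 3, byrow = TRUE),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3, byrow = TRUE),
    x = matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE))
}

world_center <- function(geom) {
  geom <- geometry_of(geom)
  geom$origin + (geom$dim - 1) / 2 * geom$spacing
}

#' Apply a rigid transform to a volume
#'
#' The volume content is moved forward by `translation_mm` and rotated by
#' `rotation_deg` about the volume's world center (angles about the z, y
#' and x axes, applied in that order); the result is backward-resampled
#' onto the volume's own geometry.
#'
#' @param vol an `image_volume` or `dose_grid`.
#' @param translation_mm length-3 `(tz, ty, tx)` in mm.
#' @param rotation_deg length-3 `(rz, ry, rx)` in degrees.
#' @return The transformed volume.
#' @export
apply_rigid <- function(vol, translation_mm = c(0, 0, 0),
                        rotation_deg = c(0, 0, 0)) {
  stopifnot(all(is.finite(translation_mm)), all(is.finite(rotation_deg)))
  R <- rot3("z", rotation_deg[1]) %*% rot3("y", rotation_deg[2]) %*%
    rot3("x", rotation_deg[3])
  cen <- world_center(vol)
  # forward motion p -> R (p - c) + c + T; backward transform is its inverse
  Ri <- t(R)
  t_back <- affine_transform(Ri, cen - Ri %*% (cen + translation_mm))
  apply_affine(vol, t_back)
}

#' Apply an affine transform
#'
#' Volumes and dose grids are backward-resampled through `t` onto
#' `geom` (their own geometry by default); landmark sets get their
#' floating-frame coordinates pulled into the registered frame through
#' the inverse of `t`, keeping correspondence with a volume resampled
#' through `t`.
#'
#' @param obj an `image_volume`, `dose_grid` or `landmark_set`.
#' @param t an [affine_transform()].
#' @param geom optional output [grid_geometry()] for volumes.
#' @return Transformed object of the same class.
#' @export
apply_affine <- function(obj, t, geom = NULL) UseMethod("apply_affine")

#' @export
apply_affine.scalar_volume <- function(obj, t, geom = NULL) {
  geom <- geometry_of(if (is.null(geom)) obj else geom)
  w <- cpp_affine_resample(as.numeric(obj$data), dim(obj$data),
                           obj$spacing, obj$origin,
                           geom$dim, geom$spacing, geom$origin,
                           t$matrix, as.numeric(t$translation))
  out <- obj
  out$data <- array(w, geom$dim)
  out$spacing <- geom$spacing
  out$origin <- geom$origin
  out
}

#' @export
apply_affine.landmark_set <- function(obj, t, geom = NULL) {
  ti <- affine_invert(t)
  flt <- affine_apply_points(ti, lm_flt_points(obj))
  out <- obj
  out$flt_z <- flt[, 1]; out$flt_y <- flt[, 2]; out$flt_x <- flt[, 3]
  out
}

#' Convert an affine transform to a deformation field
#'
#' Samples the displacement `world_to_voxel(t(voxel_to_world(x))) - x` at
#' every voxel of `geom`. Used to hand the preregistration result to the
#' deformable stage as its initial field, so the floating image is
#' interpolated only once when the final field is applied (no
#' resample-after-affine double interpolation).
#'
#' @param t an [affine_transform()].
#' @param geom the reference [grid_geometry()] (or object carrying one).
#' @return A [deformation_field()] on `geom`, in voxel units.
#' @export
affine_to_field <- function(t, geom) {
  geom <- geometry_of(geom)
  d <- geom$dim
  idx <- list(array(seq_len(d[1]) - 1, d),
              array(rep(seq_len(d[2]) - 1, each = d[1]), d),
              array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), d))
  W <- lapply(1:3, function(k) geom$origin[k] + idx[[k]] * geom$spacing[k])
  M <- t$matrix; b <- t$translation
  f <- zero_field(geom)
  for (k in 1:3) {
    qk <- M[k, 1] * W[[1]] + M[k, 2] * W[[2]] + M[k, 3] * W[[3]] + b[k]
    f$disp[, , , k] <- (qk - geom$origin[k]) / geom$spacing[k] - idx[[k]]
  }
  f
}

#' Affine registration parameters
#'
#' @param levels multi-resolution depth (level 1 = full resolution).
#' @param max_iters iteration budget per level (scalar or vector, fine to
#'   coarse; a shorter vector is extended with its last value).
#' @param tol relative MSE improvement below which a level stops.
#' @param sampling_fraction fraction of metric voxels used, taken as a
#'   deterministic stride (1 = all voxels, no randomness).
#' @return An `affine_reg_params` list.
#' @export
affine_reg_params <- function(levels = 3L, max_iters = c(20L, 60L, 120L),
                              tol = 1e-10, sampling_fraction = 1) {
  stopifnot(levels >= 1, all(max_iters >= 1), tol > 0,
            sampling_fraction > 0, sampling_fraction <= 1)
  structure(list(levels = as.integer(levels),
                 max_iters = as.integer(max_iters),
                 tol = tol,
                 sampling_fraction = sampling_fraction),
            class = "affine_reg_params")
}

# theta (scaled 12-vector) -> affine_transform about a fixed center
theta_to_affine <- function(theta, cen, s_m = 0.01, s_t = 1) {
  M <- diag(3) + matrix(theta[1:9] * s_m, 3, 3, byrow = TRUE)
  b <- cen - M %*% cen + theta[10:12] * s_t
  list(M = M, b = as.numeric(b))
}

#' Automatic affine registration
#'
#' Multi-resolution minimization of the mean-squared HU difference between
#' the reference and the affinely-resampled floating image over the twelve
#' affine parameters (quasi-Newton BFGS with finite-difference gradients
#' at each pyramid level, coarse to fine). The metric is evaluated on the
#' overlap domain only -- output voxels whose source position falls
#' outside the floating volume are excluded -- and within `body_mask` when
#' given. Deterministic (no random sampling).
#'
#' @param floating,reference `image_volume`s on the same geometry.
#' @param params an [affine_reg_params()].
#' @param body_mask optional [structure_mask()] on the reference geometry.
#' @return An [affine_transform()] with attributes `mse_trace` (per-level
#'   initial/final metric values, coarse first) and `mse_initial` /
#'   `mse_final` at full resolution.
#' @export
affine_register <- function(floating, reference, params = affine_reg_params(),
                            body_mask = NULL) {
  if (!same_geometry(floating, reference))
    stop_geometry_mismatch(floating, reference, "floating and reference")
  ref_pyr <- build_pyramid(reference, params$levels)
  flt_pyr <- build_pyramid(floating, params$levels)
  mask_pyr <- NULL
  if (!is.null(body_mask)) {
    mv <- reference; mv$data <- array(as.numeric(body_mask$mask), dim(body_mask$mask))
    mask_pyr <- lapply(build_pyramid(mv, params$levels), function(m) m$data > 0.5)
  }
  cen <- world_center(reference)
  theta <- rep(0, 12)
  traces <- list()
  for (lev in seq(params$levels, 1)) {
    refl <- ref_pyr[[lev]]; fltl <- flt_pyr[[lev]]
    geom <- geometry_of(refl)
    refv <- as.numeric(refl$data)
    keep <- if (is.null(mask_pyr)) rep(TRUE, length(refv))
            else as.logical(mask_pyr[[lev]])
    if (params$sampling_fraction < 1) {
      stride <- max(1L, round(1 / params$sampling_fraction))
      sel <- rep(FALSE, length(refv))
      sel[seq(1, length(refv), by = stride)] <- TRUE
      keep <- keep & sel
    }
    cost <- function(th) {
      tr <- theta_to_affine(th, cen)
      w <- cpp_affine_resample_na(as.numeric(fltl$data), dim(fltl$data),
                                  fltl$spacing, fltl$origin,
                                  geom$dim, geom$spacing, geom$origin,
                                  tr$M, tr$b)
      d <- (w - refv)[keep]
      mean(d * d, na.rm = TRUE)
    }
    f0 <- cost(theta)
    maxit <- params$max_iters[min(lev, length(params$max_iters))]
    res <- stats::optim(theta, cost, method = "BFGS",
                        control = list(maxit = maxit, reltol = params$tol,
                                       ndeps = rep(0.02, 12)))
    if (res$value <= f0) theta <- res$par
    traces[[length(traces) + 1L]] <- c(initial = f0, final = min(res$value, f0))
  }
  tr <- theta_to_affine(theta, cen)
  out <- affine_transform(tr$M, tr$b)
  # full-resolution before/after metric for reporting
  full_cost <- function(trf) {
    geom <- geometry_of(reference)
    w <- cpp_affine_resample_na(as.numeric(floating$data), dim(floating$data),
                                floating$spacing, floating$origin,
                                geom$dim, geom$spacing, geom$origin,
                                trf$matrix, trf$translation)
    d <- w - as.numeric(reference$data)
    if (!is.null(body_mask)) d <- d[body_mask$mask]
    mean(d * d, na.rm = TRUE)
  }
  mse0 <- full_cost(affine_transform())
  mse1 <- full_cost(out)
  if (mse1 > mse0)
    stop(sprintf(
      "affine registration diverged: final MSE %.4g exceeds initial %.4g (per-level trace: %s)",
      mse1, mse0,
      paste(vapply(traces, function(t) sprintf("%.4g->%.4g", t[1], t[2]), ""),
            collapse = ", ")))
  attr(out, "mse_trace") <- traces
  attr(out, "mse_initial") <- mse0
  attr(out, "mse_final") <- mse1
  out
}
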