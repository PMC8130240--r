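#' @useDynLib ctdosemap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm quantile optim
#' @importFrom utils read.csv write.csv head
NULL

# ---- geometry -------------------------------------------------------------

#' Grid geometry
#'
#' A light container describing a regular 3D grid: dimensions, voxel spacing
#' and world origin, all in `(z, y, x)` axis order. The world frame follows
#' the DICOM patient coordinate convention with axis-aligned axial slices;
#' the world position of voxel `(i, j, k)` (0-based) is
#' `origin + c(i, j, k) * spacing`.
#'
#' @param dim integer vector of 3 grid sizes `(nz, ny, nx)`.
#' @param spacing numeric vector of 3 voxel sizes in mm, all `> 0`.
#' @param origin numeric vector of 3 world coordinates (mm) of voxel
#'   `(0, 0, 0)`.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(dim, spacing, origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(dim) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing components must be finite and > 0")
  if (any(!is.finite(origin))) stop("origin must be finite")
  structure(list(dim = dim, spacing = spacing, origin = origin),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: dim (z,y,x) = %s, spacing = %s mm, origin = %s mm\n",
              paste(x$dim, collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Extract the grid geometry of a volume-like object
#' @param x an `image_volume`, `dose_grid`, `deformation_field` or
#'   `structure_mask`.
#' @return A [grid_geometry()].
#' @export
geometry_of <- function(x) {
  if (inherits(x, "grid_geometry")) return(x)
  d <- if (inherits(x, "deformation_field")) dim(x$disp)[1:3]
       else if (inherits(x, "structure_mask")) dim(x$mask)
       else dim(x$data)
  grid_geometry(d, x$spacing, x$origin)
}

same_geometry <- function(a, b, tol = 1e-6) {
  ga <- geometry_of(a); gb <- geometry_of(b)
  all(ga$dim == gb$dim) &&
    all(abs(ga$spacing - gb$spacing) <= tol) &&
    all(abs(ga$origin - gb$origin) <= tol)
}

stop_geometry_mismatch <- function(a, b, what = "objects") {
  ga <- geometry_of(a); gb <- geometry_of(b)
  stop(sprintf(
    "geometry mismatch between %s: [dim %s, spacing %s, origin %s] vs [dim %s, spacing %s, origin %s]",
    what,
    paste(ga$dim, collapse = "x"), paste(format(ga$spacing), collapse = ","),
    paste(format(ga$origin), collapse = ","),
    paste(gb$dim, collapse = "x"), paste(format(gb$spacing), collapse = ","),
    paste(format(gb$origin), collapse = ",")))
}

#' Convert world coordinates (mm) to continuous voxel coordinates
#'
#' Both directions are the per-axis affine relation
#' `voxel = (mm - origin) / spacing`, in `(z, y, x)` order.
#'
#' @param geom a [grid_geometry()] or any object with one.
#' @param p numeric vector of 3, or an `n x 3` matrix, of world coordinates.
#' @return Same shape as `p`, in continuous 0-based voxel units.
#' @export
world_to_voxel <- function(geom, p) {
  geom <- geometry_of(geom)
  if (is.matrix(p)) {
    if (any(!is.finite(p))) stop("non-finite coordinate")
    sweep(sweep(p, 2, geom$origin, "-"), 2, geom$spacing, "/")
  } else {
    if (any(!is.finite(p))) stop("non-finite coordinate")
    (p - geom$origin) / geom$spacing
  }
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(geom, p) {
  geom <- geometry_of(geom)
  if (is.matrix(p)) {
    if (any(!is.finite(p))) stop("non-finite coordinate")
    sweep(sweep(p, 2, geom$spacing, "*"), 2, geom$origin, "+")
  } else {
    if (any(!is.finite(p))) stop("non-finite coordinate")
    p * geom$spacing + geom$origin
  }
}

# ---- containers -----------------------------------------------------------

new_scalar_volume <- function(data, spacing, origin, class2) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (any(dim(data) < 2L)) stop("every axis must have length >= 2")
  g <- grid_geometry(dim(data), spacing, origin)
  structure(list(data = data, spacing = g$spacing, origin = g$origin),
            class = c(class2, "scalar_volume"))
}

#' CT image volume
#'
#' A 3D grid of Hounsfield units with spacing/origin metadata, the substrate
#' of the deformable registration. Dimension order is `(z, y, x)` throughout
#' the package.
#'
#' @param data 3D numeric array of HU, dims `(nz, ny, nx)`, all finite.
#' @param spacing,origin grid geometry in mm, `(z, y, x)` order.
#' @return An `image_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (any(!is.finite(data))) stop("HU values must be finite")
  new_scalar_volume(data, spacing, origin, "image_volume")
}

#' Absorbed dose grid
#'
#' A 3D grid of absorbed dose in Gy with its own geometry, which may differ
#' from the CT geometry (doses are resampled lazily where needed).
#'
#' @param data 3D numeric array of dose in Gy, all finite and `>= 0`.
#' @param spacing,origin grid geometry in mm, `(z, y, x)` order.
#' @return A `dose_grid`.
#' @export
dose_grid <- function(data, spacing, origin = c(0, 0, 0)) {
  if (any(!is.finite(data))) stop("dose values must be finite")
  if (any(data < 0)) stop("dose values must be >= 0")
  new_scalar_volume(data, spacing, origin, "dose_grid")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<%s> dim (z,y,x) = %s, spacing = %s mm, range [%.6g, %.6g]\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Deformation field
#'
#' Per-voxel 3-component displacement defined on the reference grid, stored
#' in voxel units of that grid with component order `(dz, dy, dx)` along the
#' fourth array dimension. Backward-warping semantics: output voxel `x`
#' reads the input at `x + disp(x)`.
#'
#' @param disp 4D numeric array, dims `(nz, ny, nx, 3)`, finite.
#' @param spacing,origin geometry of the reference grid the field lives on.
#' @return A `deformation_field`.
#' @export
deformation_field <- function(disp, spacing, origin = c(0, 0, 0)) {
  d <- dim(disp)
  if (length(d) != 4L || d[4] != 3L) stop("disp must be a (nz,ny,nx,3) array")
  if (any(!is.finite(disp))) stop("displacements must be finite")
  g <- grid_geometry(d[1:3], spacing, origin)
  structure(list(disp = disp, spacing = g$spacing, origin = g$origin),
            class = "deformation_field")
}

#' Zero deformation field on a geometry
#' @param geom a [grid_geometry()] or object carrying one.
#' @return A `deformation_field` of all-zero displacement.
#' @export
zero_field <- function(geom) {
  geom <- geometry_of(geom)
  deformation_field(array(0, c(geom$dim, 3L)), geom$spacing, geom$origin)
}

#' @export
print.deformation_field <- function(x, ...) {
  n <- sqrt(x$disp[, , , 1]^2 + x$disp[, , , 2]^2 + x$disp[, , , 3]^2)
  cat(sprintf("<deformation_field> dim %s, |disp| mean %.4g max %.4g voxel\n",
              paste(dim(x$disp)[1:3], collapse = "x"), mean(n), max(n)))
  invisible(x)
}

#' Binary structure mask
#'
#' A named boolean voxel mask on a stated geometry (an organ, the body
#' contour, or the applicator). Empty masks are allowed but flagged via
#' the `empty` field.
#'
#' @param name structure name (ROI name).
#' @param mask 3D logical array.
#' @param spacing,origin geometry the mask is defined on.
#' @return A `structure_mask`.
#' @export
structure_mask <- function(name, mask, spacing, origin = c(0, 0, 0)) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  mask <- array(as.logical(mask), dim(mask))
  g <- grid_geometry(dim(mask), spacing, origin)
  structure(list(name = as.character(name), mask = mask,
                 spacing = g$spacing, origin = g$origin,
                 empty = !any(mask)),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d voxels%s\n", x$name, sum(x$mask),
              if (x$empty) " (EMPTY)" else ""))
  invisible(x)
}

#' Paired anatomical landmarks
#'
#' Labelled pairs of corresponding 3D points in the reference (BRT planning)
#' and floating (EBRT planning) frames, in world mm, `(z, y, x)` order.
#'
#' @param df data frame with columns `label`, `ref_z`, `ref_y`, `ref_x`,
#'   `flt_z`, `flt_y`, `flt_x` (mm).
#' @return A `landmark_set` (a data frame subclass).
#' @export
landmark_set <- function(df) {
  need <- c("label", "ref_z", "ref_y", "ref_x", "flt_z", "flt_y", "flt_x")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing landmark column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$label <- as.character(df$label)
  if (nrow(df) < 1L) stop("landmark set must contain at least one point")
  if (anyDuplicated(df$label)) stop("duplicate landmark label(s): ",
    paste(unique(df$label[duplicated(df$label)]), collapse = ", "))
  num <- as.matrix(df[, -1])
  if (any(!is.finite(num))) stop("landmark coordinates must be finite")
  class(df) <- c("landmark_set", "data.frame")
  df
}

lm_ref_points <- function(lm) as.matrix(lm[, c("ref_z", "ref_y", "ref_x")])
lm_flt_points <- function(lm) as.matrix(lm[, c("flt_z", "flt_y", "flt_x")])

#' Fractionation scheme
#'
#' Parameters of the linear-quadratic EQD2 conversion for one treatment
#' course: number of fractions and the tissue alpha/beta ratio (10 Gy is the
#' conventional tumor-response value, 3 Gy the late-effect value for organs
#' at risk).
#'
#' @param n_fractions positive integer fraction count of the course.
#' @param alpha_beta_gy alpha/beta ratio in Gy, `> 0`.
#' @param total_dose_gy optional prescription dose in Gy.
#' @return A `fractionation_scheme`.
#' @export
fractionation_scheme <- function(n_fractions, alpha_beta_gy,
                                 total_dose_gy = NA_real_) {
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1L) stop("n_fractions must be >= 1")
  if (!is.finite(alpha_beta_gy) || alpha_beta_gy <= 0)
    stop("alpha_beta_gy must be > 0")
  structure(list(total_dose_gy = total_dose_gy, n_fractions = n_fractions,
                 alpha_beta_gy = alpha_beta_gy),
            class = "fractionation_scheme")
}

#' Case bundle
#'
#' The full input set for one treatment pair: reference (BRT-frame) and
#' floating (EBRT-frame) CTs, their dose grids, structure masks, paired
#' landmarks and the fractionation schemes of both courses.
#'
#' @param reference_ct,floating_ct `image_volume`s.
#' @param reference_dose,floating_dose `dose_grid`s (BRT and EBRT course).
#' @param masks named list of `structure_mask`s.
#' @param landmarks a [landmark_set()].
#' @param fractionation list with elements `ebrt` and `brt`, each a
#'   [fractionation_scheme()].
#' @return A `case_bundle`.
#' @export
case_bundle <- function(reference_ct, floating_ct, reference_dose = NULL,
                        floating_dose = NULL, masks = list(),
                        landmarks = NULL, fractionation = NULL) {
  stopifnot(inherits(reference_ct, "image_volume"),
            inherits(floating_ct, "image_volume"))
  if (!is.null(fractionation)) {
    stopifnot(inherits(fractionation$ebrt, "fractionation_scheme"),
              inherits(fractionation$brt, "fractionation_scheme"))
  }
  structure(list(reference_ct = reference_ct, floating_ct = floating_ct,
                 reference_dose = reference_dose, floating_dose = floating_dose,
                 masks = masks, landmarks = landmarks,
                 fractionation = fractionation),
            class = "case_bundle")
}

# run a block with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
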