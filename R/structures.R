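#' Voxelized structure on a regular grid
#'
#' The basic anatomical container: a named binary mask (target, OAR or body
#' outline) on a regular 3D grid. All structures of one case share a grid.
#'
#' @section Coordinate conventions:
#' All coordinates are millimetres in a fixed patient-based frame:
#' \itemize{
#'   \item array dimension 1 / +x: patient left
#'   \item array dimension 2 / +y: anterior (towards the source at gantry 0)
#'   \item array dimension 3 / +z: superior (cranio-caudal axis)
#' }
#' Voxel centres sit at \code{origin + (index - 1) * spacing}; \code{origin}
#' is the centre of voxel \code{[1,1,1]}. The machine isocenter is a point in
#' the same frame; geometric computations use coordinates relative to it.
#' A voxel belongs to a shape iff its centre is inside the shape.
#'
#' @param name structure name.
#' @param role one of \code{"target"}, \code{"oar"}, \code{"body"}.
#' @param mask logical 3D array.
#' @param spacing_mm numeric length-3, voxel spacing, all > 0.
#' @param origin_mm numeric length-3, centre of the first voxel.
#' @param isocenter_mm numeric length-3, isocenter position; default the grid
#'   centre.
#' @return an object of class \code{structure_volume}.
#' @export
structure_volume <- function(name, role = c("oar", "target", "body"),
                             mask, spacing_mm, origin_mm = NULL,
                             isocenter_mm = c(0, 0, 0)) {
  role <- match.arg(role)
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (any(spacing_mm <= 0)) stop("spacing must be positive")
  if (is.null(origin_mm)) origin_mm <- -spacing_mm * (dim(mask) - 1) / 2
  if (role == "target" && !any(mask)) stop("empty structure")
  obj <- list(name = as.character(name), role = role,
              mask = array(as.logical(mask), dim(mask)),
              spacing_mm = spacing_mm,
              origin_mm = as.numeric(origin_mm),
              isocenter_mm = as.numeric(isocenter_mm))
  class(obj) <- "structure_volume"
  obj
}

#' @export
print.structure_volume <- function(x, ...) {
  cat(sprintf("<structure_volume> %s (%s): %d voxels, grid %s, spacing %s mm\n",
              x$name, x$role, sum(x$mask),
              paste(dim(x$mask), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x")))
  invisible(x)
}

# n x 3 matrix of voxel-centre coordinates (mm, relative to isocenter) of all
# TRUE voxels. The workhorse for every projection.
voxel_coords <- function(sv) {
  idx <- which(sv$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty structure")
  sweep(sweep(idx - 1, 2, sv$spacing_mm, "*"), 2,
        sv$origin_mm - sv$isocenter_mm, "+")
}

# volume of one voxel in cm^3
voxel_cc <- function(sv) prod(sv$spacing_mm) / 1000

structure_volume_cc <- function(sv) sum(sv$mask) * voxel_cc(sv)

same_grid <- function(a, b) {
  identical(dim(a$mask), dim(b$mask)) &&
    isTRUE(all.equal(a$spacing_mm, b$spacing_mm)) &&
    isTRUE(all.equal(a$origin_mm, b$origin_mm))
}

#' Scalar dose distribution on a regular grid
#'
#' @param dose numeric 3D array (or 2D matrix for planar dose), Gy, >= 0.
#' @param spacing_mm voxel spacing (recycled to the array dimensionality).
#' @param origin_mm centre of the first voxel; default grid-centred.
#' @param prescription_gy prescribed dose for the associated dose level, Gy.
#' @return an object of class \code{dose_grid}.
#' @export
dose_grid <- function(dose, spacing_mm, origin_mm = NULL,
                      prescription_gy = NA_real_) {
  if (is.matrix(dose)) dose <- array(dose, c(dim(dose), 1L))
  stopifnot(is.array(dose), length(dim(dose)) == 3L)
  if (any(dose < 0)) stop("invalid dose")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (is.null(origin_mm)) origin_mm <- -spacing_mm * (dim(dose) - 1) / 2
  obj <- list(dose = dose, spacing_mm = spacing_mm,
              origin_mm = as.numeric(origin_mm),
              prescription_gy = prescription_gy)
  class(obj) <- "dose_grid"
  obj
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels, max %.2f Gy, prescription %s Gy\n",
              paste(dim(x$dose), collapse = "x"), max(x$dose),
              format(x$prescription_gy)))
  invisible(x)
}

# doses of the voxels of a structure; grids must be aligned
structure_doses <- function(dose, sv) {
  if (!identical(dim(dose$dose), dim(sv$mask)))
    dose <- resample_dose(dose, sv)
  dose$dose[sv$mask]
}

# trilinear resampling of a dose grid onto a structure's grid (the clinical
# situation: 2.5 mm dose grid vs 2 mm CT grid)
resample_dose <- function(dose, sv) {
  dm <- dim(sv$mask)
  ax <- lapply(1:3, function(k) sv$origin_mm[k] + (seq_len(dm[k]) - 1) * sv$spacing_mm[k])
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  vals <- interp_trilinear(dose$dose, dose$spacing_mm, dose$origin_mm, g)
  vals[is.na(vals)] <- 0
  dose_grid(array(vals, dm), sv$spacing_mm, sv$origin_mm, dose$prescription_gy)
}

# trilinear interpolation of array `a` (spacing/origin in mm) at points
# (n x 3, mm); NA outside the grid
interp_trilinear <- function(a, spacing, origin, pts) {
  dm <- dim(a)
  u <- sweep(sweep(pts, 2, origin, "-"), 2, spacing, "/") + 1  # 1-based index
  out <- rep(NA_real_, nrow(pts))
  ok <- u[, 1] >= 1 - 1e-9 & u[, 1] <= dm[1] + 1e-9 &
        u[, 2] >= 1 - 1e-9 & u[, 2] <= dm[2] + 1e-9 &
        u[, 3] >= 1 - 1e-9 & u[, 3] <= dm[3] + 1e-9
  if (!any(ok)) return(out)
  u <- pmin(pmax(u, 1), matrix(dm, nrow(pts), 3, byrow = TRUE))
  # degenerate (singleton) dimensions interpolate trivially
  lo <- pmin(floor(u), matrix(pmax(dm - 1, 1), nrow(pts), 3, byrow = TRUE))
  fr <- u - lo
  l <- lo[ok, , drop = FALSE]; f <- fr[ok, , drop = FALSE]
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    i1 <- pmin(l[, 1] + dx, dm[1]); i2 <- pmin(l[, 2] + dy, dm[2])
    i3 <- pmin(l[, 3] + dz, dm[3])
    acc <- acc + w * a[cbind(i1, i2, i3)]
  }
  out[ok] <- acc
  out
}
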