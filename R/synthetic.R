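# Synthetic anthropomorphic-like fixtures: phantoms, analytic dose
# distributions and lagged delivery logs. Everything downstream is testable
# against these without clinical data.

#' Ellipsoid shape descriptor
#'
#' @param center_mm centre in the patient frame, mm.
#' @param semiaxes_mm length-3 semi-axes, mm (a sphere when all equal).
#' @return shape descriptor usable in \code{\link{phantom_spec}}.
#' @export
shape_ellipsoid <- function(center_mm, semiaxes_mm) {
  semiaxes_mm <- as.numeric(semiaxes_mm)
  if (length(semiaxes_mm) == 1L) semiaxes_mm <- rep(semiaxes_mm, 3L)
  stopifnot(all(semiaxes_mm > 0))
  list(type = "ellipsoid", center = as.numeric(center_mm),
       semiaxes = semiaxes_mm)
}

#' Cylinder shape descriptor (axis-aligned)
#'
#' @param center_mm centre, mm.
#' @param radius_mm cylinder radius, mm.
#' @param half_length_mm half-extent along the cylinder axis, mm.
#' @param axis one of \code{"x"}, \code{"y"}, \code{"z"}.
#' @export
shape_cylinder <- function(center_mm, radius_mm, half_length_mm, axis = "z") {
  stopifnot(radius_mm > 0, half_length_mm > 0, axis %in% c("x", "y", "z"))
  list(type = "cylinder", center = as.numeric(center_mm),
       radius = radius_mm, half_length = half_length_mm,
       axis = match(axis, c("x", "y", "z")))
}

shape_bbox <- function(shape) {
  if (shape$type == "ellipsoid") {
    rbind(shape$center - shape$semiaxes, shape$center + shape$semiaxes)
  } else {
    half <- rep(shape$radius, 3)
    half[shape$axis] <- shape$half_length
    rbind(shape$center - half, shape$center + half)
  }
}

# voxel-centre membership test; pts is n x 3 (mm)
shape_contains <- function(shape, pts) {
  if (shape$type == "ellipsoid") {
    q <- sweep(sweep(pts, 2, shape$center, "-"), 2, shape$semiaxes, "/")
    rowSums(q^2) <= 1
  } else {
    rel <- sweep(pts, 2, shape$center, "-")
    ax <- shape$axis
    perp <- setdiff(1:3, ax)
    rel[, perp[1]]^2 + rel[, perp[2]]^2 <= shape$radius^2 &
      abs(rel[, ax]) <= shape$half_length
  }
}

#' Specification of a synthetic phantom
#'
#' @param grid_shape integer length-3, voxel counts.
#' @param spacing_mm voxel spacing (scalar or length-3), mm, > 0.
#' @param target list \code{(name, shape)} for the target.
#' @param oars list of lists \code{(name, shape, role_tag)} with
#'   \code{role_tag} in \code{"parallel"}/\code{"serial"} (informational).
#' @param body optional body shape descriptor.
#' @param seed integer seed (the generator is deterministic; the seed is part
#'   of the spec so derived stochastic fixtures inherit it).
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape, spacing_mm, target, oars = list(),
                         body = NULL, seed = 1L) {
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1), all(spacing_mm > 0))
  obj <- list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
              target = target, oars = oars, body = body,
              seed = as.integer(seed))
  class(obj) <- "phantom_spec"
  obj
}

#' Default head-and-neck-like phantom specification
#'
#' A stylised geometry creating an asymmetric gantry-table cost structure:
#' a 25 mm-radius spherical target at the isocenter, two 15 mm
#' "parotid-like" spheres at +/-45 mm laterally, a 5 mm-radius x 120 mm
#' "cord-like" posterior cylinder, and a 90 x 110 x 150 mm body ellipsoid,
#' on a 2 mm isotropic grid.
#'
#' @param spacing_mm grid spacing, default 2 mm isotropic.
#' @param seed integer seed.
#' @return a \code{\link{phantom_spec}}.
#' @export
hn_phantom_spec <- function(spacing_mm = 2, seed = 1L) {
  ext <- c(100, 120, 160)  # half-extents of the grid, mm
  shape <- 2 * floor(ext / spacing_mm) + 1
  phantom_spec(
    grid_shape = shape, spacing_mm = spacing_mm,
    target = list(name = "PTV", shape = shape_ellipsoid(c(0, 0, 0), 25)),
    oars = list(
      list(name = "parotid_R", shape = shape_ellipsoid(c(-45, 0, 0), 15),
           role_tag = "parallel"),
      list(name = "parotid_L", shape = shape_ellipsoid(c(45, 0, 0), 15),
           role_tag = "parallel"),
      list(name = "cord", shape = shape_cylinder(c(0, -40, 0), 5, 60, "z"),
           role_tag = "serial")),
    body = shape_ellipsoid(c(0, 0, 0), c(90, 110, 150)),
    seed = seed)
}

#' Voxelize a phantom specification into structure volumes
#'
#' A voxel belongs to a shape iff its centre is inside the shape. The grid is
#' centred on the isocenter.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return named list of \code{\link{structure_volume}}s (target first, then
#'   OARs, then body when present).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  sp <- spec$spacing_mm
  origin <- -sp * (dm - 1) / 2
  lims <- rbind(origin - sp / 2, origin + (dm - 1) * sp + sp / 2)
  check_inside <- function(shape, name) {
    bb <- shape_bbox(shape)
    if (any(bb[1, ] < lims[1, ]) || any(bb[2, ] > lims[2, ]))
      stop(sprintf("geometry out of bounds: %s", name))
  }
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(dm[k]) - 1) * sp[k])
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  vox <- function(shape) array(shape_contains(shape, pts), dm)
  out <- list()
  check_inside(spec$target$shape, spec$target$name)
  out[[spec$target$name]] <- structure_volume(
    spec$target$name, "target", vox(spec$target$shape), sp, origin)
  for (o in spec$oars) {
    check_inside(o$shape, o$name)
    sv <- structure_volume(o$name, "oar", vox(o$shape), sp, origin)
    sv$role_tag <- if (is.null(o$role_tag)) "parallel" else o$role_tag
    out[[o$name]] <- sv
  }
  if (!is.null(spec$body)) {
    check_inside(spec$body, "body")
    out[["body"]] <- structure_volume("body", "body", vox(spec$body), sp,
                                      origin)
  }
  out
}

#' Specification of an analytic dose distribution
#'
#' @param mode \code{"uniform"}, \code{"spherical-falloff"} or
#'   \code{"linear-gradient"}.
#' @param plateau_gy plateau dose, Gy, >= 0.
#' @param center_mm reference point (falloff centre / gradient origin), mm.
#' @param gradient_pct_per_mm dose falloff, percent of plateau per mm.
#' @param falloff_radius_mm radius of the uniform plateau for
#'   \code{"spherical-falloff"}, mm.
#' @param axis gradient axis for \code{"linear-gradient"}.
#' @return object of class \code{dose_spec}.
#' @export
dose_spec <- function(mode = c("uniform", "spherical-falloff",
                               "linear-gradient"),
                      plateau_gy, center_mm = c(0, 0, 0),
                      gradient_pct_per_mm = 5, falloff_radius_mm = 25,
                      axis = "x") {
  mode <- match.arg(mode)
  if (plateau_gy < 0) stop("invalid dose")
  obj <- list(mode = mode, plateau_gy = plateau_gy,
              center_mm = as.numeric(center_mm),
              gradient_pct_per_mm = gradient_pct_per_mm,
              falloff_radius_mm = falloff_radius_mm,
              axis = match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z")))
  class(obj) <- "dose_spec"
  obj
}

#' Generate an analytic dose grid on a phantom grid
#'
#' Modes: \code{uniform} is constant at the plateau; \code{linear-gradient}
#' falls off linearly (percent of plateau per mm) along the stated axis
#' beyond the reference coordinate, clipped at 0; \code{spherical-falloff}
#' holds the plateau inside \code{falloff_radius_mm} of the centre and then
#' falls off linearly, clipped at 0.
#'
#' @param spec a \code{\link{dose_spec}}.
#' @param grid a \code{\link{structure_volume}} or \code{\link{dose_grid}}
#'   providing grid shape, spacing and origin.
#' @param prescription_gy prescription carried on the output grid.
#' @return a \code{\link{dose_grid}}.
#' @export
make_dose <- function(spec, grid, prescription_gy = spec$plateau_gy) {
  stopifnot(inherits(spec, "dose_spec"))
  dm <- if (inherits(grid, "structure_volume")) dim(grid$mask) else dim(grid$dose)
  sp <- grid$spacing_mm
  origin <- grid$origin_mm
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(dm[k]) - 1) * sp[k])
  d <- switch(spec$mode,
    "uniform" = array(spec$plateau_gy, dm),
    "linear-gradient" = {
      tmp <- array(0, dm)
      coord <- array(ax[[spec$axis]][slice.index(tmp, spec$axis)], dm)
      pmax(spec$plateau_gy *
             (1 - spec$gradient_pct_per_mm / 100 *
                pmax(coord - spec$center_mm[spec$axis], 0)), 0)
    },
    "spherical-falloff" = {
      pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
      r <- sqrt(rowSums(sweep(pts, 2, spec$center_mm, "-")^2))
      val <- spec$plateau_gy *
        pmax(1 - spec$gradient_pct_per_mm / 100 *
               pmax(r - spec$falloff_radius_mm, 0), 0)
      array(val, dm)
    })
  dose_grid(d, sp, origin, prescription_gy)
}

# evaluate f with a private RNG stream; restores the caller's RNG state
with_seed <- function(seed, f) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  f()
}

#' Simulate a machine delivery log for a trajectory
#'
#' Emulates the lag behaviour seen in dynamic deliveries: each rotational
#' axis trails its expected position proportionally to its instantaneous
#' speed, plus Gaussian readout noise:
#' \code{actual = expected - lag_gain * speed + N(0, noise_sd)}.
#' Timestamps assume the gantry rotates at its maximum speed.
#'
#' @param path a \code{\link{trajectory_path}} (>= 2 control points).
#' @param lag_gain seconds-equivalent lag per unit speed (deg per (deg/s)),
#'   default 0.05.
#' @param noise_sd readout noise SD, degrees, default 0.01.
#' @param seed integer seed; the log is deterministic given the seed.
#' @param gantry_speed_deg_s maximum gantry speed, default 6 deg/s.
#' @return a \code{delivery_log}: data frame with \code{time_s} and
#'   \code{<axis>_expected}/\code{<axis>_actual} columns for gantry, table
#'   and collimator.
#' @export
make_delivery_log <- function(path, lag_gain = 0.05, noise_sd = 0.01,
                              seed = 1L, gantry_speed_deg_s = 6) {
  cp <- if (inherits(path, "trajectory_path")) path$control_points else path
  stopifnot(nrow(cp) >= 2)
  dt <- abs(diff(cp$gantry_deg)) / gantry_speed_deg_s
  time_s <- c(0, cumsum(dt))
  axes <- c("gantry", "table", "collimator")
  log <- data.frame(time_s = time_s)
  with_seed(seed, function() {
    for (a in axes) {
      exp_v <- cp[[paste0(a, "_deg")]]
      v <- central_speed(exp_v, time_s)
      act <- exp_v - lag_gain * v +
        if (noise_sd > 0) stats::rnorm(length(v), 0, noise_sd) else 0
      log[[paste0(a, "_expected")]] <<- exp_v
      log[[paste0(a, "_actual")]] <<- act
    }
  })
  class(log) <- c("delivery_log", "data.frame")
  log
}

# central finite differences over timestamps, one-sided at the ends
central_speed <- function(x, t) {
  n <- length(x)
  if (n < 2) stop("need >= 2 records")
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) / (t[2] - t[1])
  v[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  v
}
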