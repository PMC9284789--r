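#' Beam geometry for one gantry/table combination
#'
#' @section Machine angle conventions:
#' Angles follow an IEC 61217-style convention, expressed in the fixed
#' patient frame documented in \code{\link{structure_volume}} (the grid never
#' moves; table rotation instead rotates the beam about the vertical axis):
#' \itemize{
#'   \item gantry rotates about the longitudinal (+z) axis; at gantry 0,
#'     table 0 the source is anterior and the beam travels along (0, -1, 0).
#'   \item table rotation is about the vertical (+y) axis through the
#'     isocenter; rotations compose table-then-gantry.
#' }
#'
#' @param gantry_deg gantry angle, wrapped to [0, 360).
#' @param table_deg table (couch) rotation, in [-90, 90].
#' @param sad_mm source-axis distance, default 1000.
#' @return object of class \code{beam_geometry}.
#' @export
beam_geometry <- function(gantry_deg, table_deg = 0, sad_mm = 1000) {
  stopifnot(sad_mm > 0)
  if (table_deg < -90 - 1e-9 || table_deg > 90 + 1e-9)
    stop("table angle out of [-90, 90]")
  obj <- list(gantry_deg = wrap360(gantry_deg), table_deg = table_deg,
              sad_mm = sad_mm)
  class(obj) <- "beam_geometry"
  obj
}

# rotation about the vertical (y) axis by t degrees
rot_y <- function(t_deg) {
  t <- deg2rad(t_deg)
  matrix(c(cos(t), 0, -sin(t),
           0, 1, 0,
           sin(t), 0, cos(t)), 3, 3)
}

#' Unit beam direction (source towards isocenter)
#'
#' @param geometry a \code{\link{beam_geometry}}.
#' @return numeric length-3 unit vector in the patient frame.
#' @export
beam_direction <- function(geometry) {
  g <- deg2rad(geometry$gantry_deg)
  d0 <- c(-sin(g), -cos(g), 0)
  as.numeric(rot_y(geometry$table_deg) %*% d0)
}

# Orthonormal BEV basis (u, v, d): u is the BEV x (collimator-unrotated leaf
# travel) direction, v the BEV y. u is built from d x z_hat, falling back to
# d x y_hat when the beam is (numerically) parallel to the longitudinal axis.
bev_basis <- function(geometry) {
  d <- beam_direction(geometry)
  ref <- c(0, 0, 1)
  u <- c(d[2] * ref[3] - d[3] * ref[2],
         d[3] * ref[1] - d[1] * ref[3],
         d[1] * ref[2] - d[2] * ref[1])
  if (sqrt(sum(u^2)) < 1e-8) {
    ref <- c(0, 1, 0)
    u <- c(d[2] * ref[3] - d[3] * ref[2],
           d[3] * ref[1] - d[1] * ref[3],
           d[1] * ref[2] - d[2] * ref[1])
  }
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v, d = d)
}
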