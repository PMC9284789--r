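# Angle helpers. All angles are degrees.

deg2rad <- function(x) x * pi / 180

#' Wrap an angle to the half-open interval [-180, 180)
#'
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles in degrees.
#' @export
wrap180 <- function(x) {
  ((x + 180) %% 360) - 180
}

#' Wrap an angle to [0, 360)
#'
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles in degrees.
#' @export
wrap360 <- function(x) x %% 360

#' Shortest signed angular difference a - b
#'
#' Used wherever an axis is circular (gantry, collimator): the difference
#' between 359 and 1 degrees is +2, not -358.
#'
#' @param a,b numeric vectors of angles in degrees.
#' @return signed differences in (-180, 180].
#' @export
circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}
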