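# DVHs and plan-quality endpoints.

#' Cumulative dose-volume histogram of a structure
#'
#' @param dose a \code{\link{dose_grid}} aligned with (or resampled to) the
#'   structure grid.
#' @param structure a non-empty \code{\link{structure_volume}}.
#' @return object of class \code{dvh}: sorted voxel doses, structure volume
#'   (cc) and an evaluation function \code{volume_at(d)} returning the
#'   relative volume receiving at least d Gy.
#' @export
dvh <- function(dose, structure) {
  if (!any(structure$mask)) stop("empty structure")
  doses <- structure_doses(dose, structure)
  sorted <- sort(doses, decreasing = TRUE)
  obj <- list(doses_sorted = sorted,
              volume_cc = length(sorted) * voxel_cc(structure),
              voxel_cc = voxel_cc(structure),
              structure = structure$name)
  class(obj) <- "dvh"
  obj
}

#' Relative volume receiving at least a dose
#'
#' @param x a \code{\link{dvh}}.
#' @param dose_gy threshold dose(s), Gy.
#' @return fraction(s) of the structure volume in [0, 1].
#' @export
endpoint_Vx <- function(x, dose_gy) {
  vapply(dose_gy, function(d) mean(x$doses_sorted >= d), numeric(1))
}

#' Dose to the hottest x percent of the volume
#'
#' D_x% is the smallest dose received by at least x percent of the
#' structure volume, linearly interpolated between the bracketing order
#' statistics of the voxel doses.
#'
#' @param x a \code{\link{dvh}}.
#' @param x_percent volume percentage(s) in (0, 100].
#' @return dose(s), Gy.
#' @export
endpoint_Dx <- function(x, x_percent) {
  s <- x$doses_sorted
  n <- length(s)
  vapply(x_percent, function(p) {
    stopifnot(p > 0, p <= 100)
    k <- p / 100 * n   # fractional rank into the descending order statistics
    if (k <= 1) return(s[1])
    lo <- floor(k); fr <- k - lo
    if (lo >= n) return(s[n])
    s[lo] * (1 - fr) + s[lo + 1] * fr
  }, numeric(1))
}

#' Near-maximum dose D_cc (default 0.03 cc)
#'
#' Minimum dose within the hottest \code{cc} cm^3: voxels are accumulated in
#' decreasing dose order and the value is interpolated within the voxel in
#' which the cumulative volume crosses \code{cc}.
#'
#' @param dose a \code{\link{dose_grid}}.
#' @param structure a \code{\link{structure_volume}}.
#' @param cc hot volume in cm^3, default 0.03.
#' @return dose, Gy.
#' @export
endpoint_D_cc <- function(dose, structure, cc = 0.03) {
  h <- dvh(dose, structure)
  if (cc > h$volume_cc) stop("volume exceeds structure")
  s <- h$doses_sorted
  k <- cc / h$voxel_cc           # fractional number of hottest voxels
  if (k <= 1) return(s[1])
  lo <- floor(k); fr <- k - lo
  if (lo >= length(s)) return(s[length(s)])
  s[lo] * (1 - fr) + s[lo + 1] * fr
}

#' Mean structure dose
#'
#' @inheritParams endpoint_D_cc
#' @return mean dose, Gy.
#' @export
mean_dose <- function(dose, structure) {
  mean(structure_doses(dose, structure))
}

#' Normalize a dose grid to a target-coverage rule
#'
#' Scales the whole distribution by one factor so that
#' \code{"D95_100"}: target D95% equals 100% of the prescription, or
#' \code{"D97_99"}: target D97% equals 99% of the prescription.
#'
#' @param dose a \code{\link{dose_grid}} with a prescription.
#' @param target target \code{\link{structure_volume}}.
#' @param rule \code{"D95_100"} (default) or \code{"D97_99"}.
#' @return the rescaled \code{dose_grid}.
#' @export
normalize_dose <- function(dose, target, rule = c("D95_100", "D97_99")) {
  rule <- match.arg(rule)
  stopifnot(is.finite(dose$prescription_gy), dose$prescription_gy > 0)
  h <- dvh(dose, target)
  cur <- endpoint_Dx(h, if (rule == "D95_100") 95 else 97)
  if (cur <= 0) stop("degenerate dose")
  goal <- if (rule == "D95_100") dose$prescription_gy else
    0.99 * dose$prescription_gy
  dose$dose <- dose$dose * (goal / cur)
  dose
}

#' Paddick conformity index
#'
#' CI = TV_PIV^2 / (TV * PIV), with TV the target volume, PIV the volume
#' receiving at least the prescription and TV_PIV their intersection; 0 when
#' no voxel reaches the prescription.
#'
#' @param dose a \code{\link{dose_grid}}.
#' @param target target \code{\link{structure_volume}}.
#' @param prescription_gy prescription dose; defaults to the grid's.
#' @return CI in [0, 1].
#' @export
ci_paddick <- function(dose, target, prescription_gy = dose$prescription_gy) {
  if (!any(target$mask)) stop("empty structure")
  d <- if (identical(dim(dose$dose), dim(target$mask))) dose else
    resample_dose(dose, target)
  piv <- d$dose >= prescription_gy
  tv <- sum(target$mask)
  npiv <- sum(piv)
  if (npiv == 0) return(0)
  tv_piv <- sum(piv & target$mask)
  tv_piv^2 / (tv * npiv)
}

#' Homogeneity index HI95 = V95% - V105%
#'
#' Difference between the target volume fractions receiving at least 95%
#' and at least 105% of the prescription, in percent of the target volume
#' (100 for a perfectly homogeneous prescription dose).
#'
#' @inheritParams ci_paddick
#' @return HI in percent.
#' @export
hi95 <- function(dose, target, prescription_gy = dose$prescription_gy) {
  h <- dvh(dose, target)
  100 * (endpoint_Vx(h, 0.95 * prescription_gy) -
           endpoint_Vx(h, 1.05 * prescription_gy))
}

#' Plan-quality report for one dose level
#'
#' @param dose a \code{\link{dose_grid}}.
#' @param target target structure.
#' @param oars named list of OAR structures.
#' @param prescription_gy prescription dose.
#' @return nested list with target metrics (D95, D5, CI, HI) and per-OAR
#'   mean dose / D_0.03cc.
#' @export
plan_metrics_report <- function(dose, target, oars = list(),
                                prescription_gy = dose$prescription_gy) {
  ht <- dvh(dose, target)
  rep <- list(
    target = list(
      name = target$name,
      volume_cc = ht$volume_cc,
      D95_gy = endpoint_Dx(ht, 95),
      D5_gy = endpoint_Dx(ht, 5),
      mean_gy = mean_dose(dose, target),
      ci_paddick = ci_paddick(dose, target, prescription_gy),
      hi95_pct = hi95(dose, target, prescription_gy)),
    oars = lapply(oars, function(o) {
      list(name = o$name,
           mean_gy = mean_dose(dose, o),
           D0.03cc_gy = endpoint_D_cc(dose, o,
                                      cc = min(0.03, structure_volume_cc(o))))
    }))
  class(rep) <- "plan_metrics_report"
  rep
}
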