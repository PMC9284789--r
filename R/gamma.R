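# Global gamma-index dose comparison.

#' Gamma-analysis criteria
#'
#' @param dose_tolerance_pct dose-difference criterion, percent of the
#'   global maximum of the reference distribution, default 2.
#' @param dta_mm distance-to-agreement criterion, mm, default 2.
#' @param low_dose_threshold_pct points with reference dose below this
#'   percent of the reference maximum are excluded from the passing-rate
#'   denominator, default 10.
#' @param search_step_frac evaluated-dose sub-sampling step as a fraction of
#'   DTA, default 0.1.
#' @param search_radius_frac search radius cap as a multiple of DTA,
#'   default 3.
#' @return object of class \code{gamma_criteria}.
#' @export
gamma_criteria <- function(dose_tolerance_pct = 2, dta_mm = 2,
                           low_dose_threshold_pct = 10,
                           search_step_frac = 0.1, search_radius_frac = 3) {
  stopifnot(dose_tolerance_pct > 0, dta_mm > 0, low_dose_threshold_pct > 0,
            search_step_frac > 0, search_radius_frac > 0)
  obj <- list(dose_tol = dose_tolerance_pct, dta = dta_mm,
              threshold = low_dose_threshold_pct,
              step_frac = search_step_frac, radius_frac = search_radius_frac)
  class(obj) <- "gamma_criteria"
  obj
}

# shift-interpolate a 2D matrix by a fractional index offset (s1, s2);
# cells whose source falls outside the grid become NA
shift_interp2 <- function(m, s1, s2) {
  n1 <- nrow(m); n2 <- ncol(m)
  i1 <- seq_len(n1) + s1
  i2 <- seq_len(n2) + s2
  l1 <- floor(i1); f1 <- i1 - l1
  l2 <- floor(i2); f2 <- i2 - l2
  get_row <- function(idx) {
    out <- matrix(NA_real_, n1, n2)
    ok <- idx >= 1 & idx <= n1
    out[ok, ] <- m[idx[ok], , drop = FALSE]
    out
  }
  a <- get_row(l1); b <- get_row(l1 + 1L)
  row_mix <- a * (1 - f1) + b * f1
  # handle f1 == 0 rows where l1+1 may be out of range
  z <- f1 == 0
  if (any(z)) row_mix[z, ] <- a[z, ]
  get_col <- function(mm, idx) {
    out <- matrix(NA_real_, n1, n2)
    ok <- idx >= 1 & idx <= n2
    out[, ok] <- mm[, idx[ok], drop = FALSE]
    out
  }
  a2 <- get_col(row_mix, l2); b2 <- get_col(row_mix, l2 + 1L)
  out <- a2 * (1 - f2) + b2 * f2
  z2 <- f2 == 0
  if (any(z2)) out[, z2] <- a2[, z2]
  out
}

#' Gamma map between two planar dose distributions
#'
#' Global gamma analysis: for every reference point with dose at or above
#' the low-dose threshold,
#' \deqn{\gamma(r) = \min_{r'} \sqrt{ (|r-r'|/DTA)^2 +
#'   ((D_e(r') - D_r(r)) / \Delta D)^2 }}
#' where \eqn{\Delta D} is the dose tolerance as a fraction of the
#' reference-distribution maximum (global normalization), and the minimum
#' runs over evaluated-dose positions on a sub-grid of step
#' \code{search_step_frac * DTA} within \code{search_radius_frac * DTA},
#' with bilinear interpolation of the evaluated dose.
#'
#' Both inputs are planar \code{\link{dose_grid}}s (single-slice arrays or
#' matrices) with equal spacing; the evaluated grid may be offset from the
#' reference grid (the offset is folded into the search).
#'
#' @param reference,evaluated \code{\link{dose_grid}}s (2D).
#' @param criteria a \code{\link{gamma_criteria}}.
#' @return object of class \code{gamma_result}: \code{gamma} matrix (NA
#'   below threshold), \code{evaluated_mask}, \code{criteria}.
#' @export
gamma_map <- function(reference, evaluated, criteria = gamma_criteria()) {
  ref <- drop(reference$dose)
  ev <- drop(evaluated$dose)
  if (is.null(dim(ref))) ref <- matrix(ref, ncol = 1)
  if (is.null(dim(ev))) ev <- matrix(ev, ncol = 1)
  sp_r <- reference$spacing_mm[1:2]
  sp_e <- evaluated$spacing_mm[1:2]
  if (max(abs(sp_r - sp_e)) > 1e-9)
    stop("reference and evaluated grids must share spacing")
  off_mm <- reference$origin_mm[1:2] - evaluated$origin_mm[1:2]
  dmax <- max(ref)
  if (dmax <= 0) stop("reference distribution has no dose")
  dd <- criteria$dose_tol / 100 * dmax
  thr <- criteria$threshold / 100 * dmax
  dta <- criteria$dta
  step <- criteria$step_frac * dta
  radius <- criteria$radius_frac * dta
  offs <- seq(-radius, radius, by = step)
  grid <- expand.grid(dx = offs, dy = offs)
  grid <- grid[grid$dx^2 + grid$dy^2 <= radius^2 + 1e-9, ]
  # make sure the zero offset is present
  if (!any(grid$dx == 0 & grid$dy == 0)) grid <- rbind(grid, c(0, 0))
  gamma2 <- matrix(Inf, nrow(ref), ncol(ref))
  any_valid <- matrix(FALSE, nrow(ref), ncol(ref))
  for (k in seq_len(nrow(grid))) {
    dx <- grid$dx[k]; dy <- grid$dy[k]
    dist2 <- (dx^2 + dy^2) / dta^2
    s1 <- (off_mm[1] + dx) / sp_r[1]
    s2 <- (off_mm[2] + dy) / sp_r[2]
    ev_s <- shift_interp2(ev, s1, s2)
    cand <- dist2 + ((ev_s - ref) / dd)^2
    upd <- !is.na(cand) & cand < gamma2
    gamma2[upd] <- cand[upd]
    any_valid <- any_valid | !is.na(cand)
  }
  if (!any(any_valid)) stop("no overlap")
  g <- sqrt(gamma2)
  g[!any_valid] <- NA_real_
  eval_mask <- ref >= thr
  g_out <- g
  g_out[!eval_mask] <- NA_real_
  obj <- list(gamma = g_out, evaluated_mask = eval_mask & any_valid,
              criteria = criteria, reference_max = dmax)
  class(obj) <- "gamma_result"
  obj
}

#' Gamma passing rate
#'
#' @param result a \code{\link{gamma_map}} result.
#' @return percentage of evaluated points with gamma <= 1.
#' @export
passing_rate <- function(result) {
  g <- result$gamma[result$evaluated_mask]
  g <- g[!is.na(g)]
  if (length(g) == 0) stop("nothing above threshold")
  100 * mean(g <= 1)
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %d evaluated points, passing rate %.1f%% (%g%%/%g mm, threshold %g%%)\n",
              sum(x$evaluated_mask), passing_rate(x), x$criteria$dose_tol,
              x$criteria$dta, x$criteria$threshold))
  invisible(x)
}
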