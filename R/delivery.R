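# Mechanical-accuracy analysis of delivery logs: expected-vs-actual
# deviations, RMS/max statistics, and speed-deviation correlation.

angular_axes <- c("gantry", "table", "collimator")

log_axes <- function(log) {
  cols <- names(log)
  exp_cols <- grep("_expected$", cols, value = TRUE)
  sub("_expected$", "", exp_cols)
}

#' Expected-vs-actual deviations for one axis
#'
#' Angular axes use the shortest signed angular difference (so an expected
#' 359 with an actual 1 is a +2 degree deviation).
#'
#' @param log a \code{delivery_log} data frame with
#'   \code{<axis>_expected}/\code{<axis>_actual} columns.
#' @param axis axis name, e.g. \code{"table"} or \code{"leaf_3"}.
#' @return numeric vector of deviations (actual - expected).
#' @export
axis_deviations <- function(log, axis) {
  ecol <- paste0(axis, "_expected"); acol <- paste0(axis, "_actual")
  if (!all(c(ecol, acol) %in% names(log))) stop("unknown axis")
  if (axis %in% angular_axes) circ_diff(log[[acol]], log[[ecol]])
  else log[[acol]] - log[[ecol]]
}

#' Axis speed from expected positions
#'
#' Central finite differences of the expected value over the timestamps
#' (one-sided at the end points).
#'
#' @inheritParams axis_deviations
#' @return numeric vector of speeds (deg/s or mm/s).
#' @export
axis_speed <- function(log, axis) {
  ecol <- paste0(axis, "_expected")
  if (!ecol %in% names(log)) stop("unknown axis")
  t <- log$time_s
  if (length(t) < 2 || any(diff(t) <= 0)) stop("invalid log")
  central_speed(log[[ecol]], t)
}

#' Mechanical-accuracy report for a delivery log
#'
#' For every axis in the log: RMS and maximum absolute deviation between
#' expected and actual values, and the Pearson correlation between axis
#' speed and deviation (two-sided p-value via the standard t transform).
#' Correlations are reported as NA with \code{correlation_defined = FALSE}
#' when speed or deviation has zero variance. MLC leaves (columns
#' \code{leaf_<i>_*}) are summarized as the mean and maximum of the
#' per-leaf RMS deviations.
#'
#' @param log a \code{delivery_log}.
#' @return object of class \code{axis_accuracy_report}: per-axis data frame
#'   and, when leaves are present, \code{mlc} with \code{mean_rms} and
#'   \code{max_rms}.
#' @export
accuracy_report <- function(log) {
  axes <- log_axes(log)
  leaf <- grepl("^leaf_", axes)
  main <- axes[!leaf]
  rows <- lapply(main, function(a) {
    dev <- axis_deviations(log, a)
    sp <- axis_speed(log, a)
    rms <- sqrt(mean(dev^2))
    mx <- max(abs(dev))
    if (stats::sd(sp) == 0 || stats::sd(dev) == 0) {
      r <- NA_real_; p <- NA_real_; def <- FALSE
    } else {
      ct <- stats::cor.test(sp, dev)
      r <- unname(ct$estimate); p <- ct$p.value; def <- TRUE
    }
    data.frame(axis = a, rms = rms, max_abs = mx, correlation = r,
               p_value = p, correlation_defined = def)
  })
  out <- list(axes = do.call(rbind, rows))
  if (any(leaf)) {
    leaf_rms <- vapply(axes[leaf], function(a)
      sqrt(mean(axis_deviations(log, a)^2)), numeric(1))
    out$mlc <- list(mean_rms = mean(leaf_rms), max_rms = max(leaf_rms),
                    n_leaves = sum(leaf))
  }
  class(out) <- "axis_accuracy_report"
  out
}

#' @export
print.axis_accuracy_report <- function(x, ...) {
  cat("<axis_accuracy_report>\n")
  print(x$axes, row.names = FALSE)
  if (!is.null(x$mlc))
    cat(sprintf("MLC (%d leaves): mean RMS %.3f, max RMS %.3f mm\n",
                x$mlc$n_leaves, x$mlc$mean_rms, x$mlc$max_rms))
  invisible(x)
}
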