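# Gradient-constrained minimum-cost path search over angle maps, smoothing,
# duplication strategies and deliverability checks.

# --- generic column-wise A* (zero heuristic, i.e. Dijkstra) ----------------
# cost: n_col x n_row matrix (Inf = excluded); angles: row angles (deg);
# max_step_deg: max |angle change| between consecutive columns; circular:
# wrap the row axis; start_row: optional forced start; tie_ref: angle whose
# proximity breaks remaining ties.
# Path cost is the SUM of entered cell costs (start column included);
# ties are broken by least total angular travel, then by least sum of
# |angle - tie_ref| over the path, then by node id (deterministic).
astar_columns <- function(cost, angles, max_step_deg, circular = FALSE,
                          start_row = NULL, tie_ref = 0) {
  ncol_ <- nrow(cost)   # columns of the search = rows of the matrix (gantry)
  nrow_ <- ncol(cost)   # search rows = angle samples
  if (nrow_ != length(angles)) stop("angle axis mismatch")
  adiff <- function(a, b) if (circular) abs(circ_diff(a, b)) else abs(a - b)
  tie_dist <- if (circular) abs(circ_diff(angles, tie_ref)) else
    abs(angles - tie_ref)
  # precompute allowed row transitions
  steps <- outer(angles, angles, function(a, b)
    if (circular) abs(circ_diff(a, b)) else abs(a - b))
  allowed <- steps <= max_step_deg + 1e-9
  nid <- function(col, row) (col - 1L) * nrow_ + row
  best1 <- matrix(Inf, ncol_, nrow_)
  best2 <- matrix(Inf, ncol_, nrow_)
  best3 <- matrix(Inf, ncol_, nrow_)
  parent <- matrix(NA_integer_, ncol_, nrow_)
  done <- matrix(FALSE, ncol_, nrow_)
  # binary min-heap with lexicographic (f1, f2, f3, id) keys, inlined as
  # local parallel vectors (lazy deletion; function-call overhead matters
  # at production map sizes)
  cap <- 4096L
  hf1 <- numeric(cap); hf2 <- numeric(cap); hf3 <- numeric(cap)
  hid <- integer(cap); hn <- 0L
  h_less <- function(i, j) {
    if (hf1[i] != hf1[j]) return(hf1[i] < hf1[j])
    if (hf2[i] != hf2[j]) return(hf2[i] < hf2[j])
    if (hf3[i] != hf3[j]) return(hf3[i] < hf3[j])
    hid[i] < hid[j]
  }
  h_push <- function(f1, f2, f3, id) {
    n <- hn + 1L
    if (n > length(hf1)) {
      hf1 <<- c(hf1, numeric(length(hf1)))
      hf2 <<- c(hf2, numeric(length(hf2)))
      hf3 <<- c(hf3, numeric(length(hf3)))
      hid <<- c(hid, integer(length(hid)))
    }
    hf1[n] <<- f1; hf2[n] <<- f2; hf3[n] <<- f3; hid[n] <<- id
    hn <<- n
    while (n > 1L) {
      p <- n %/% 2L
      if (h_less(n, p)) {
        t1 <- hf1[n]; hf1[n] <<- hf1[p]; hf1[p] <<- t1
        t1 <- hf2[n]; hf2[n] <<- hf2[p]; hf2[p] <<- t1
        t1 <- hf3[n]; hf3[n] <<- hf3[p]; hf3[p] <<- t1
        t2 <- hid[n]; hid[n] <<- hid[p]; hid[p] <<- t2
        n <- p
      } else break
    }
  }
  h_pop <- function() {
    out <- c(hf1[1], hf2[1], hf3[1], hid[1])
    n <- hn
    hf1[1] <<- hf1[n]; hf2[1] <<- hf2[n]; hf3[1] <<- hf3[n]
    hid[1] <<- hid[n]
    hn <<- n - 1L
    i <- 1L
    repeat {
      l <- 2L * i; r <- l + 1L
      m <- i
      if (l <= hn && h_less(l, m)) m <- l
      if (r <= hn && h_less(r, m)) m <- r
      if (m == i) break
      t1 <- hf1[i]; hf1[i] <<- hf1[m]; hf1[m] <<- t1
      t1 <- hf2[i]; hf2[i] <<- hf2[m]; hf2[m] <<- t1
      t1 <- hf3[i]; hf3[i] <<- hf3[m]; hf3[m] <<- t1
      t2 <- hid[i]; hid[i] <<- hid[m]; hid[m] <<- t2
      i <- m
    }
    out
  }
  start_rows <- if (is.null(start_row)) seq_len(nrow_) else start_row
  for (r in start_rows) {
    if (!is.finite(cost[1, r])) next
    best1[1, r] <- cost[1, r]; best2[1, r] <- 0; best3[1, r] <- tie_dist[r]
    h_push(best1[1, r], 0, tie_dist[r], nid(1L, r))
  }
  goal <- NULL
  while (hn > 0L) {
    top <- h_pop()
    id <- as.integer(top[4])
    col <- (id - 1L) %/% nrow_ + 1L
    row <- (id - 1L) %% nrow_ + 1L
    if (done[col, row]) next
    # stale entry?
    if (top[1] > best1[col, row] + 1e-12) next
    done[col, row] <- TRUE
    if (col == ncol_) { goal <- c(col, row); break }
    nxt <- which(allowed[row, ] & is.finite(cost[col + 1L, ]) &
                   !done[col + 1L, ])
    if (length(nxt)) {
      g1 <- best1[col, row] + cost[col + 1L, nxt]
      g2 <- best2[col, row] + steps[row, nxt]
      g3 <- best3[col, row] + tie_dist[nxt]
      o1 <- best1[col + 1L, nxt]; o2 <- best2[col + 1L, nxt]
      o3 <- best3[col + 1L, nxt]
      better <- g1 < o1 | (g1 == o1 & (g2 < o2 | (g2 == o2 & g3 < o3)))
      for (k in which(better)) {
        r2 <- nxt[k]
        best1[col + 1L, r2] <- g1[k]; best2[col + 1L, r2] <- g2[k]
        best3[col + 1L, r2] <- g3[k]
        parent[col + 1L, r2] <- row
        h_push(g1[k], g2[k], g3[k], nid(col + 1L, r2))
      }
    }
  }
  if (is.null(goal)) stop("no feasible path")
  rows <- integer(ncol_)
  rows[ncol_] <- goal[2]
  for (c in rev(seq_len(ncol_ - 1L)))
    rows[c] <- parent[c + 1L, rows[c + 1L]]
  list(rows = rows, angle_deg = angles[rows],
       cost = best1[ncol_, goal[2]], travel = best2[ncol_, goal[2]])
}

#' Minimum-cost gantry-table path (A*, zero heuristic)
#'
#' Finds the table-angle sequence (one table angle per gantry control point)
#' minimizing the summed cell cost of the combined GT map, subject to the
#' kinematic gradient limit (default 3 degrees of table rotation per degree
#' of gantry rotation) and avoiding exclusion cells. The zero heuristic
#' makes the search Dijkstra-equivalent and therefore provably optimal;
#' equal-cost ties are broken by least total table travel, then by table
#' angles closest to 0.
#'
#' @param map a \code{\link{build_gt_map}} result.
#' @param gradient_limit_deg_per_deg max table rotation per degree of gantry
#'   rotation, default 3.
#' @return object of class \code{gt_path}: \code{gantry_deg},
#'   \code{table_deg}, \code{rows}, \code{cost}, \code{travel}.
#' @export
astar_gt <- function(map, gradient_limit_deg_per_deg = 3) {
  dg <- abs(diff(map$gantry_deg))
  step_g <- if (length(dg)) stats::median(dg) else 2
  cost <- map$combined
  cost[map$excluded] <- Inf
  res <- astar_columns(cost, map$table_deg,
                       max_step_deg = gradient_limit_deg_per_deg * step_g)
  out <- list(gantry_deg = map$gantry_deg, table_deg = res$angle_deg,
              rows = res$rows, cost = res$cost, travel = res$travel)
  class(out) <- "gt_path"
  out
}

#' Minimum-width collimator path along a GT path (A*, zero heuristic)
#'
#' As \code{\link{astar_gt}} but on the collimator-gantry field-width map;
#' the collimator axis is circular (wrap at +/-180, widths are 180-degree
#' periodic) and the step constraint uses the shortest signed angular
#' difference.
#'
#' @param map a \code{\link{build_gc_map}} result.
#' @param gradient_limit_deg_per_deg max collimator rotation per degree of
#'   gantry rotation, default 3.
#' @param start_deg optional forced collimator start angle (snapped to the
#'   nearest axis sample).
#' @return object of class \code{gc_path}: \code{gantry_deg},
#'   \code{collimator_deg}, \code{cost}.
#' @export
astar_gc <- function(map, gradient_limit_deg_per_deg = 3, start_deg = NULL) {
  dg <- abs(diff(map$gantry_deg))
  step_g <- if (length(dg)) stats::median(dg) else 2
  start_row <- NULL
  if (!is.null(start_deg))
    start_row <- which.min(abs(circ_diff(map$collimator_deg, start_deg)))
  res <- astar_columns(map$width, map$collimator_deg,
                       max_step_deg = gradient_limit_deg_per_deg * step_g,
                       circular = TRUE, start_row = start_row)
  out <- list(gantry_deg = map$gantry_deg, collimator_deg = res$angle_deg,
              rows = res$rows, cost = res$cost, travel = res$travel)
  class(out) <- "gc_path"
  out
}

#' Moving-average path smoothing
#'
#' Centred moving average used to avoid abrupt table/collimator motion. An
#' even window is realised as the symmetric window of half-width
#' \code{floor(window/2)} (so the default 10-point window averages up to 11
#' points in the interior); at the sequence ends the window shrinks
#' symmetrically. Output length equals input length, and smoothing never
#' increases the maximum absolute per-step increment.
#'
#' @param x numeric sequence (angles in degrees).
#' @param window_points window size in points, default 10.
#' @return smoothed numeric sequence of the same length.
#' @export
smooth_path <- function(x, window_points = 10) {
  n <- length(x)
  stopifnot(n >= 1, window_points >= 1)
  half <- floor(window_points / 2)
  if (half == 0 || n == 1) return(x)
  vapply(seq_len(n), function(i) {
    k <- min(half, i - 1L, n - i)
    mean(x[(i - k):(i + k)])
  }, numeric(1))
}

# Push a smoothed table sequence out of exclusion cells: for every gantry
# column whose nearest-cell lookup is excluded, move to the nearest feasible
# table angle in that column, then clamp to the gradient limit relative to
# neighbours and re-check. Returns the adjusted sequence.
project_to_feasible <- function(table_seq, map, max_step_deg) {
  tab_axis <- map$table_deg
  n <- length(table_seq)
  out <- table_seq
  excl_col <- function(i) map$excluded[i, ]
  is_excluded <- function(i, ang) {
    r <- which.min(abs(tab_axis - ang))
    map$excluded[i, r]
  }
  for (i in seq_len(n)) {
    if (is_excluded(i, out[i])) {
      feas <- which(!excl_col(i))
      if (!length(feas)) stop("no feasible path")
      out[i] <- tab_axis[feas[which.min(abs(tab_axis[feas] - out[i]))]]
    }
  }
  # gradient repair sweeps (projection may have broken the limit)
  for (pass in 1:4) {
    ok <- TRUE
    for (i in 2:n) {
      d <- out[i] - out[i - 1]
      if (abs(d) > max_step_deg + 1e-9) {
        cand <- out[i - 1] + sign(d) * max_step_deg
        if (!is_excluded(i, cand)) out[i] <- cand else ok <- FALSE
        ok <- ok && abs(out[i] - out[i - 1]) <= max_step_deg + 1e-9
      }
    }
    for (i in (n - 1):1) {
      d <- out[i] - out[i + 1]
      if (abs(d) > max_step_deg + 1e-9) {
        cand <- out[i + 1] + sign(d) * max_step_deg
        if (!is_excluded(i, cand)) out[i] <- cand else ok <- FALSE
      }
    }
    if (ok) break
  }
  out
}

#' Trajectory path (ordered machine control points)
#'
#' @param gantry_deg,table_deg,collimator_deg equal-length control-point
#'   angle sequences.
#' @param jaw_x1_mm,jaw_x2_mm secondary collimator jaw positions along the
#'   BEV x direction, mm (x1 <= x2).
#' @param recipe name of the OAR recipe that produced the path.
#' @param duplication duplication tag.
#' @return object of class \code{trajectory_path} with a
#'   \code{control_points} data frame and metadata.
#' @export
trajectory_path <- function(gantry_deg, table_deg, collimator_deg,
                            jaw_x1_mm = NA_real_, jaw_x2_mm = NA_real_,
                            recipe = "path", duplication = "none") {
  n <- length(gantry_deg)
  stopifnot(length(table_deg) == n, length(collimator_deg) == n)
  cp <- data.frame(index = seq_len(n) - 1L,
                   gantry_deg = gantry_deg, table_deg = table_deg,
                   collimator_deg = collimator_deg,
                   jaw_x1_mm = rep_len(jaw_x1_mm, n),
                   jaw_x2_mm = rep_len(jaw_x2_mm, n))
  obj <- list(control_points = cp, recipe = recipe, duplication = duplication)
  class(obj) <- "trajectory_path"
  obj
}

#' @export
print.trajectory_path <- function(x, ...) {
  cp <- x$control_points
  cat(sprintf("<trajectory_path> %s [%s]: %d control points, gantry %g..%g, table %g..%g\n",
              x$recipe, x$duplication, nrow(cp), cp$gantry_deg[1],
              cp$gantry_deg[nrow(cp)], min(cp$table_deg), max(cp$table_deg)))
  invisible(x)
}

# BEV footprint extent of the target along the collimator-rotated x axis for
# each control point; returns cbind(lo, hi) in mm
footprint_x_extent <- function(target, gantry_deg, table_deg, collimator_deg,
                               sad_mm = 1000) {
  coords <- voxel_coords(target)
  pad <- max(target$spacing_mm) / 2
  n <- length(gantry_deg)
  lo <- hi <- numeric(n)
  for (i in seq_len(n)) {
    geo <- beam_geometry(gantry_deg[i], table_deg[i], sad_mm)
    pr <- project_points(coords, geo)
    c_ <- deg2rad(collimator_deg[i])
    p <- pr$xy[, 1] * cos(c_) + pr$xy[, 2] * sin(c_)
    lo[i] <- min(p) - pad; hi[i] <- max(p) + pad
  }
  cbind(lo, hi)
}

#' Expand a trajectory with a duplication strategy
#'
#' \code{split-field} returns two copies whose jaws partition the target's
#' BEV x-extent at its midpoint with a configurable overlap;
#' \code{collimator-offset-90} returns the original plus a copy with a
#' constant +90 degree collimator offset (wrapped) and re-fitted jaws;
#' \code{none} returns the path unchanged.
#'
#' @param path a \code{\link{trajectory_path}}.
#' @param strategy \code{"none"}, \code{"split-field"} or
#'   \code{"collimator-offset-90"}.
#' @param target target \code{\link{structure_volume}} (jaw fitting).
#' @param overlap_mm jaw overlap at the field junction, default 5.
#' @param sad_mm source-axis distance.
#' @return list of \code{trajectory_path}s.
#' @export
duplicate_paths <- function(path, strategy = c("none", "split-field",
                                               "collimator-offset-90"),
                            target = NULL, overlap_mm = 5, sad_mm = 1000) {
  strategy <- match.arg(strategy)
  if (strategy == "none") return(list(path))
  if (is.null(target)) stop("target required for duplication")
  cp <- path$control_points
  if (strategy == "split-field") {
    ext <- footprint_x_extent(target, cp$gantry_deg, cp$table_deg,
                              cp$collimator_deg, sad_mm)
    mid <- (ext[, 1] + ext[, 2]) / 2
    a <- path; b <- path
    a$control_points$jaw_x1_mm <- ext[, 1]
    a$control_points$jaw_x2_mm <- mid + overlap_mm / 2
    b$control_points$jaw_x1_mm <- mid - overlap_mm / 2
    b$control_points$jaw_x2_mm <- ext[, 2]
    a$duplication <- "split-field-A"; b$duplication <- "split-field-B"
    list(a, b)
  } else {
    b <- path
    b$control_points$collimator_deg <- wrap180(cp$collimator_deg + 90)
    ext <- footprint_x_extent(target, cp$gantry_deg, cp$table_deg,
                              b$control_points$collimator_deg, sad_mm)
    b$control_points$jaw_x1_mm <- ext[, 1]
    b$control_points$jaw_x2_mm <- ext[, 2]
    path$duplication <- "crot-A"; b$duplication <- "crot-B"
    list(path, b)
  }
}

#' Check a trajectory against axis speed limits
#'
#' Verifies that, with the gantry at its maximum speed, no axis must move
#' faster than its own limit between consecutive control points.
#'
#' @param path a \code{\link{trajectory_path}}.
#' @param limits_deg_s named numeric: maximum axis speeds, defaults
#'   \code{c(gantry = 6, table = 20, collimator = 20)}.
#' @return list with \code{feasible} flag and \code{violations} data frame
#'   (empty iff feasible).
#' @export
check_deliverability <- function(path,
                                 limits_deg_s = c(gantry = 6, table = 20,
                                                  collimator = 20)) {
  cp <- path$control_points
  dg <- diff(cp$gantry_deg)
  if (!(all(dg > 0) || all(dg < 0)))
    stop("gantry sequence must be monotone")
  dt_s <- abs(dg) / limits_deg_s[["gantry"]]
  viol <- list()
  for (a in c("table", "collimator")) {
    d <- if (a == "collimator") circ_diff(cp[[paste0(a, "_deg")]][-1],
                                          cp[[paste0(a, "_deg")]][-nrow(cp)])
         else diff(cp[[paste0(a, "_deg")]])
    need <- abs(d) / dt_s
    bad <- which(need > limits_deg_s[[a]] + 1e-9)
    if (length(bad))
      viol[[a]] <- data.frame(axis = a, index = bad,
                              required_deg_s = need[bad],
                              limit_deg_s = limits_deg_s[[a]])
  }
  v <- if (length(viol)) do.call(rbind, viol) else
    data.frame(axis = character(), index = integer(),
               required_deg_s = numeric(), limit_deg_s = numeric())
  list(feasible = nrow(v) == 0, violations = v)
}

#' Plan trajectories for one OAR recipe
#'
#' The full geometric pipeline: A* gantry-table path on the combined map,
#' moving-average smoothing with exclusion re-projection, collimator-gantry
#' width map and A* collimator path (also smoothed), jaw fitting, and
#' duplication-strategy expansion.
#'
#' @param gt_map a \code{\link{build_gt_map}} result.
#' @param target target \code{\link{structure_volume}}.
#' @param strategy duplication strategy (see \code{\link{duplicate_paths}}).
#' @param gradient_limit_deg_per_deg kinematic gradient limit, default 3.
#' @param window_points smoothing window, default 10.
#' @param collimator_deg collimator axis for the GC map.
#' @param recipe recipe name carried in the metadata.
#' @param overlap_mm split-field jaw overlap, default 5.
#' @return list of \code{\link{trajectory_path}}s.
#' @export
plan_trajectories <- function(gt_map, target, strategy = "none",
                              gradient_limit_deg_per_deg = 3,
                              window_points = 10,
                              collimator_deg = seq(-180, 178, by = 2),
                              recipe = "path", overlap_mm = 5) {
  dg <- abs(diff(gt_map$gantry_deg))
  step_g <- if (length(dg)) stats::median(dg) else 2
  max_step <- gradient_limit_deg_per_deg * step_g
  gt <- astar_gt(gt_map, gradient_limit_deg_per_deg)
  tab <- smooth_path(gt$table_deg, window_points)
  tab <- project_to_feasible(tab, gt_map, max_step)
  gc_map <- build_gc_map(target, gt_map$gantry_deg, tab, collimator_deg,
                         sad_mm = gt_map$sad_mm)
  gc <- astar_gc(gc_map, gradient_limit_deg_per_deg)
  # smooth the collimator on the unwrapped circle, then wrap back
  col_unwrapped <- cumsum(c(gc$collimator_deg[1],
                            circ_diff(gc$collimator_deg[-1],
                                      gc$collimator_deg[-length(gc$collimator_deg)])))
  col_smooth <- wrap180(smooth_path(col_unwrapped, window_points))
  ext <- footprint_x_extent(target, gt_map$gantry_deg, tab, col_smooth,
                            gt_map$sad_mm)
  base <- trajectory_path(gt_map$gantry_deg, tab, col_smooth,
                          jaw_x1_mm = ext[, 1], jaw_x2_mm = ext[, 2],
                          recipe = recipe)
  duplicate_paths(base, strategy, target, overlap_mm = overlap_mm,
                  sad_mm = gt_map$sad_mm)
}

#' Validate trajectory kinematic invariants
#'
#' Checks gantry monotonicity/spacing, the table and collimator gradient
#' limits, and (when a GT map is supplied) that no control point lies in an
#' exclusion cell.
#'
#' @param path a \code{\link{trajectory_path}}.
#' @param gt_map optional \code{gt_map} for exclusion checking.
#' @param gradient_limit_deg_per_deg gradient limit, default 3.
#' @return TRUE (invisibly) or an error describing the violated invariant.
#' @export
validate_trajectory <- function(path, gt_map = NULL,
                                gradient_limit_deg_per_deg = 3) {
  cp <- path$control_points
  dg <- diff(cp$gantry_deg)
  if (!(all(dg > 0) || all(dg < 0)))
    stop("gantry not strictly monotone")
  step_g <- abs(dg[1])
  if (any(abs(abs(dg) - step_g) > 1e-9))
    stop("gantry spacing not constant")
  lim <- gradient_limit_deg_per_deg * step_g + 1e-6
  if (any(abs(diff(cp$table_deg)) > lim))
    stop("table gradient limit violated")
  dcol <- abs(circ_diff(cp$collimator_deg[-1], cp$collimator_deg[-nrow(cp)]))
  if (any(dcol > lim))
    stop("collimator gradient limit violated")
  if (!is.null(gt_map)) {
    gi <- vapply(cp$gantry_deg, function(g)
      which.min(abs(circ_diff(gt_map$gantry_deg, g))), integer(1))
    ti <- vapply(cp$table_deg, function(t)
      which.min(abs(gt_map$table_deg - t)), integer(1))
    if (any(gt_map$excluded[cbind(gi, ti)]))
      stop("control point inside exclusion zone")
  }
  invisible(TRUE)
}
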