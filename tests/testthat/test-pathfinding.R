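# A* path-finding, smoothing, duplication, deliverability

test_that("zero-cost map returns the constant 0-degree path (tie-breaking)", {
  m <- raw_gt_map(matrix(0, 12, 11), table = seq(-10, 10, 2))
  p <- astar_gt(m)
  expect_equal(p$cost, 0)
  expect_equal(p$table_deg, rep(0, 12))
  expect_equal(p$travel, 0)
})

test_that("A* equals brute-force DP on random maps with exclusions", {
  set.seed(11)
  angles <- seq(-19, 19, 2)
  for (rep in 1:40) {
    cost <- matrix(runif(20 * 20), 20, 20)
    excl <- matrix(runif(400) < 0.2, 20, 20)
    cost[excl] <- Inf
    m <- raw_gt_map(cost, table = angles, excluded = excl)
    bf <- dp_min_cost(cost, angles, max_step = 6)
    if (!is.finite(bf)) {
      expect_error(astar_gt(m), "no feasible path")
    } else {
      expect_equal(astar_gt(m)$cost, bf)
    }
  }
})

test_that("an obstacle forcing a jump beyond the step limit is infeasible", {
  cost <- matrix(0, 5, 9)
  excl <- matrix(FALSE, 5, 9)
  excl[3, 1:8] <- TRUE   # only the far row open in column 3
  excl[4, 2:9] <- TRUE   # only the near row open in column 4: jump of 16 deg
  cost[excl] <- Inf
  m <- raw_gt_map(cost, table = seq(-8, 8, 2), excluded = excl)
  expect_error(astar_gt(m), "no feasible path")
})

test_that("5x5 hand-checkable map matches exhaustive enumeration", {
  set.seed(5)
  cost <- matrix(round(runif(25), 2), 5, 5)
  angles <- seq(-4, 4, 2)
  # exhaustive enumeration over all 5^5 paths with |step| <= 2 rows
  rows <- as.matrix(expand.grid(1:5, 1:5, 1:5, 1:5, 1:5))
  ok <- apply(rows, 1, function(r) all(abs(diff(r)) <= 3))
  costs <- apply(rows[ok, ], 1, function(r) sum(cost[cbind(1:5, r)]))
  m <- raw_gt_map(cost, table = angles)
  expect_equal(astar_gt(m)$cost, min(costs))
})

test_that("collimator search respects the circular axis and forced start", {
  # constant width: tie-break settles at the forced start / nearest zero
  w <- matrix(5, 10, length(seq(-180, 175, 5)))
  gc <- list(gantry_deg = seq(0, 18, 2), table_deg = rep(0, 10),
             collimator_deg = seq(-180, 175, 5), width = w, sad_mm = 1000)
  class(gc) <- "gc_map"
  p95 <- astar_gc(gc, start_deg = 95)
  expect_equal(p95$collimator_deg, rep(95, 10))
  p0 <- astar_gc(gc)
  expect_equal(p0$collimator_deg, rep(0, 10))
  # wrap-around is cheaper than the long way: path from 175 can reach -180
  w2 <- matrix(100, 3, length(seq(-180, 175, 5)))
  w2[, c(1, 72)] <- 0   # -180 and 175 are free
  gc2 <- list(gantry_deg = c(0, 2, 4), table_deg = rep(0, 3),
              collimator_deg = seq(-180, 175, 5), width = w2, sad_mm = 1000)
  class(gc2) <- "gc_map"
  p2 <- astar_gc(gc2)
  expect_equal(p2$cost, 0)
  expect_true(all(p2$collimator_deg %in% c(-180, 175)))
  # brute force agreement on a rotating-rectangle-style map
  set.seed(21)
  wid <- matrix(runif(10 * 24, 20, 80), 10, 24)
  ang <- seq(-180, 165, 15)
  gc3 <- list(gantry_deg = seq(0, 90, 10), table_deg = rep(0, 10),
              collimator_deg = ang, width = wid, sad_mm = 1000)
  class(gc3) <- "gc_map"
  # gantry step 10 deg -> max collimator step 30 deg
  expect_equal(astar_gc(gc3)$cost,
               dp_min_cost(wid, ang, max_step = 30, circular = TRUE))
})

test_that("smoothing: identity, constancy, window means, contraction", {
  expect_equal(smooth_path(c(3, 1, 4, 1, 5), 1), c(3, 1, 4, 1, 5))
  expect_equal(smooth_path(rep(7, 25), 10), rep(7, 25))
  x <- c(rep(0, 10), rep(30, 10))
  got <- smooth_path(x, 10)
  # direct window-mean arithmetic, half-width 5 shrinking at the ends
  manual <- sapply(1:20, function(i) {
    k <- min(5, i - 1, 20 - i)
    mean(x[(i - k):(i + k)])
  })
  expect_equal(got, manual)
  expect_equal(length(got), length(x))
  set.seed(31)
  for (rep in 1:50) {
    z <- cumsum(rnorm(sample(2:60, 1), sd = 4))
    zz <- smooth_path(z, sample(c(2, 5, 10, 15), 1))
    expect_lte(max(abs(diff(zz))), max(abs(diff(z))) + 1e-12)
  }
})

test_that("smoothed paths are re-projected out of exclusion zones", {
  cost <- matrix(0, 20, 11)
  excl <- matrix(FALSE, 20, 11)
  excl[10, 5:7] <- TRUE    # centre rows blocked in column 10
  cost[excl] <- Inf
  m <- raw_gt_map(cost, table = seq(-10, 10, 2), excluded = excl)
  p <- astar_gt(m)
  sm <- smooth_path(p$table_deg, 10)
  adj <- dtrtplan:::project_to_feasible(sm, m, max_step_deg = 6)
  r <- which.min(abs(m$table_deg - adj[10]))
  expect_false(m$excluded[10, r])
  expect_lte(max(abs(diff(adj))), 6 + 1e-9)
})

test_that("duplication strategies: none, split-field jaws, CRot offset", {
  ph <- concentric_phantom(r_target = 10)
  tp <- trajectory_path(seq(0, 90, 10), rep(0, 10), rep(0, 10),
                        recipe = "r")
  expect_length(duplicate_paths(tp, "none"), 1)
  sf <- duplicate_paths(tp, "split-field", ph$T, overlap_mm = 5)
  expect_length(sf, 2)
  a <- sf[[1]]$control_points; b <- sf[[2]]$control_points
  # the two jaw windows tile the footprint with a 5 mm overlap
  expect_equal(a$jaw_x2_mm - b$jaw_x1_mm, rep(5, 10))
  expect_lt(max(abs((a$jaw_x2_mm + b$jaw_x1_mm) / 2 -
                      (a$jaw_x1_mm + b$jaw_x2_mm) / 2)), 1e-9)
  expect_true(all(b$jaw_x2_mm > a$jaw_x2_mm))
  cr <- duplicate_paths(tp, "collimator-offset-90", ph$T)
  expect_length(cr, 2)
  off <- circ_diff(cr[[2]]$control_points$collimator_deg,
                   cr[[1]]$control_points$collimator_deg)
  expect_equal(off, rep(90, 10))
  # applying the offset twice returns to the start modulo 180
  twice <- wrap180(cr[[2]]$control_points$collimator_deg + 90)
  expect_equal(abs(circ_diff(twice, cr[[1]]$control_points$collimator_deg)) %% 180,
               rep(0, 10))
})

test_that("deliverability check flags axis-speed violations", {
  tp_ok <- trajectory_path(seq(0, 58, 2), seq(0, 29, 1), rep(0, 30))
  chk <- check_deliverability(tp_ok)
  expect_true(chk$feasible)
  expect_equal(nrow(chk$violations), 0)
  tab <- rep(0, 30); tab[16:30] <- 10   # 10 deg jump over one 2 deg step
  tp_bad <- trajectory_path(seq(0, 58, 2), tab, rep(0, 30))
  chk2 <- check_deliverability(tp_bad)
  expect_false(chk2$feasible)
  expect_true(15 %in% chk2$violations$index)
  expect_identical(chk2$feasible, nrow(chk2$violations) == 0)
})

test_that("trajectory validation enforces the kinematic invariants", {
  good <- trajectory_path(seq(0, 358, 2),
                          smooth_path(c(rep(0, 90), rep(30, 90)), 10),
                          rep(5, 180))
  expect_true(validate_trajectory(good))
  bad_g <- trajectory_path(c(0, 2, 2, 4), rep(0, 4), rep(0, 4))
  expect_error(validate_trajectory(bad_g), "monotone")
  bad_t <- trajectory_path(seq(0, 6, 2), c(0, 8, 0, 0), rep(0, 4))
  expect_error(validate_trajectory(bad_t), "table gradient")
})
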