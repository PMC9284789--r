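# Independent oracles and fixture builders shared across the test suite.
# These deliberately re-derive results by brute force / direct arithmetic,
# separate from the package's own code paths.

# ---- path-finding oracle: layered dynamic programming ---------------------
# Minimum total cell cost over all feasible column-paths. cost is
# n_col x n_row with Inf for excluded cells; angles are the row angles;
# max_step is the largest |angle change| per column; circular wraps rows.
dp_min_cost <- function(cost, angles, max_step, circular = FALSE) {
  nc <- nrow(cost); nr <- ncol(cost)
  dif <- function(a, b) if (circular) {
    d <- abs(a - b) %% 360; pmin(d, 360 - d)
  } else abs(a - b)
  V <- cost[1, ]
  for (cc in 2:nc) {
    Vn <- rep(Inf, nr)
    for (r in 1:nr) {
      if (!is.finite(cost[cc, r])) next
      prev <- which(dif(angles, angles[r]) <= max_step + 1e-9)
      m <- min(V[prev])
      Vn[r] <- cost[cc, r] + m
    }
    V <- Vn
  }
  min(V)
}

# ---- gamma oracle: per-point brute-force minimization ---------------------
# Independent bilinear interpolation + dense candidate search (step_mm over
# a disc of radius_mm). ref/ev are matrices on the same spacing; off_mm is
# the (ref - ev) origin offset.
bilin_at <- function(m, ix, iy) {
  # ix, iy fractional 1-based indices (vectors); NA outside
  n1 <- nrow(m); n2 <- ncol(m)
  ok <- ix >= 1 & ix <= n1 & iy >= 1 & iy <= n2
  lx <- pmin(floor(ix), n1 - 1); ly <- pmin(floor(iy), n2 - 1)
  fx <- ix - lx; fy <- iy - ly
  out <- rep(NA_real_, length(ix))
  o <- which(ok)
  if (!length(o)) return(out)
  v00 <- m[cbind(lx[o], ly[o])];     v10 <- m[cbind(lx[o] + 1, ly[o])]
  v01 <- m[cbind(lx[o], ly[o] + 1)]; v11 <- m[cbind(lx[o] + 1, ly[o] + 1)]
  out[o] <- v00 * (1 - fx[o]) * (1 - fy[o]) + v10 * fx[o] * (1 - fy[o]) +
    v01 * (1 - fx[o]) * fy[o] + v11 * fx[o] * fy[o]
  out
}

gamma_oracle_rate <- function(ref, ev, spacing, dta = 2, tol_pct = 2,
                              thr_pct = 10, step_mm = 0.1,
                              radius_mm = 3 * dta, off_mm = c(0, 0)) {
  dmax <- max(ref)
  dd <- tol_pct / 100 * dmax
  thr <- thr_pct / 100 * dmax
  offs <- seq(-radius_mm, radius_mm, by = step_mm)
  cand <- expand.grid(dx = offs, dy = offs)
  cand <- cand[cand$dx^2 + cand$dy^2 <= radius_mm^2 + 1e-9, ]
  dist2 <- (cand$dx^2 + cand$dy^2) / dta^2
  pass <- 0L; n_eval <- 0L
  for (i in seq_len(nrow(ref))) for (j in seq_len(ncol(ref))) {
    if (ref[i, j] < thr) next
    n_eval <- n_eval + 1L
    ix <- i + (off_mm[1] + cand$dx) / spacing[1]
    iy <- j + (off_mm[2] + cand$dy) / spacing[2]
    de <- bilin_at(ev, ix, iy)
    g2 <- dist2 + ((de - ref[i, j]) / dd)^2
    g2 <- g2[!is.na(g2)]
    if (length(g2) && min(g2) <= 1 + 1e-12) pass <- pass + 1L
  }
  100 * pass / n_eval
}

# ---- dose/metrics oracles -------------------------------------------------
# D_x% bracketing order statistics: the interpolated D_x% must lie between
# the doses of the two adjacent hottest-voxel counts.
dx_bracket <- function(doses, x_percent) {
  s <- sort(doses, decreasing = TRUE)
  n <- length(s)
  k <- x_percent / 100 * n
  lo <- max(1, floor(k)); hi <- min(n, ceiling(k))
  c(min(s[lo], s[hi]), max(s[lo], s[hi]))
}

# ---- fixture builders -----------------------------------------------------
two_sphere_phantom <- function(sep_mm = 50, r_target = 10, r_oar = 10,
                               spacing = 2) {
  nx <- 2 * ceiling((sep_mm + r_oar + 10) / spacing) + 1
  nyz <- 2 * ceiling((r_target + 10) / spacing) + 1
  make_phantom(phantom_spec(
    c(nx, nyz, nyz), spacing,
    target = list(name = "T", shape = shape_ellipsoid(c(0, 0, 0), r_target)),
    oars = list(list(name = "O",
                     shape = shape_ellipsoid(c(sep_mm, 0, 0), r_oar)))))
}

concentric_phantom <- function(r_target = 10, r_oar = 6, spacing = 2) {
  n <- 2 * ceiling((r_target + 6) / spacing) + 1
  make_phantom(phantom_spec(
    c(n, n, n), spacing,
    target = list(name = "T", shape = shape_ellipsoid(c(0, 0, 0), r_target)),
    oars = list(list(name = "O",
                     shape = shape_ellipsoid(c(0, 0, 0), r_oar)))))
}

# minimal gt_map wrapper around a raw cost matrix for path-finding tests
raw_gt_map <- function(cost, gantry = seq(0, by = 2,
                                          length.out = nrow(cost)),
                       table = seq(-(ncol(cost) - 1), ncol(cost) - 1,
                                   by = 2),
                       excluded = NULL) {
  if (is.null(excluded)) excluded <- matrix(FALSE, nrow(cost), ncol(cost))
  m <- list(gantry_deg = gantry, table_deg = table, combined = cost,
            excluded = excluded,
            cause = matrix("", nrow(cost), ncol(cost)), sad_mm = 1000)
  class(m) <- "gt_map"
  m
}

# random smooth 2D dose field (sum of a few Gaussian blobs)
random_smooth_dose <- function(n1, n2, spacing = 1, seed = 1,
                               base_gy = 10) {
  set.seed(seed)
  x <- (seq_len(n1) - (n1 + 1) / 2) * spacing
  y <- (seq_len(n2) - (n2 + 1) / 2) * spacing
  f <- matrix(0, n1, n2)
  for (k in 1:3) {
    cx <- runif(1, min(x), max(x)); cy <- runif(1, min(y), max(y))
    s <- runif(1, 4, 10); a <- runif(1, 0.3, 1)
    f <- f + a * outer(exp(-(x - cx)^2 / (2 * s^2)),
                       exp(-(y - cy)^2 / (2 * s^2)))
  }
  base_gy * f / max(f)
}
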