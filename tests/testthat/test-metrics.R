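# DVH and plan-quality endpoints

uniform_case <- function(gy = 50, presc = 50) {
  ph <- concentric_phantom(r_target = 10)
  d <- make_dose(dose_spec("uniform", gy), ph$T, prescription_gy = presc)
  list(ph = ph, d = d)
}

test_that("uniform dose: step DVH and textbook endpoint values", {
  cs <- uniform_case()
  h <- dvh(cs$d, cs$ph$T)
  expect_equal(endpoint_Vx(h, c(0, 25, 50)), c(1, 1, 1))
  expect_equal(endpoint_Vx(h, 50.01), 0)
  expect_equal(endpoint_Dx(h, 95), 50)
  expect_equal(endpoint_D_cc(cs$d, cs$ph$T, 0.03), 50)
  expect_equal(mean_dose(cs$d, cs$ph$T), 50)
  expect_equal(hi95(cs$d, cs$ph$T), 100)
})

test_that("two-voxel and ten-voxel order-statistic cases", {
  mask <- array(FALSE, c(4, 1, 1)); mask[1:2, 1, 1] <- TRUE
  sv <- structure_volume("s", "oar", mask, 10)   # 1 cc voxels
  arr <- array(0, c(4, 1, 1)); arr[1, 1, 1] <- 40; arr[2, 1, 1] <- 60
  d <- dose_grid(arr, 10)
  h <- dvh(d, sv)
  expect_equal(endpoint_Vx(h, 50), 0.5)   # value on (40, 60]
  expect_equal(endpoint_Vx(h, 40), 1)
  mask10 <- array(FALSE, c(10, 1, 1)); mask10[, 1, 1] <- TRUE
  sv10 <- structure_volume("s", "oar", mask10, 10)
  d10 <- dose_grid(array(1:10, c(10, 1, 1)), 10)
  h10 <- dvh(d10, sv10)
  br <- dx_bracket(1:10, 50)
  d50 <- endpoint_Dx(h10, 50)
  expect_gte(d50, br[1]); expect_lte(d50, br[2])
  expect_equal(endpoint_Dx(h10, 10), 10)  # hottest voxel exactly
})

test_that("D_x, V_x and D_cc agree with order-statistic oracles", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    mask <- array(FALSE, c(n, 1, 1)); mask[, 1, 1] <- TRUE
    sv <- structure_volume("s", "oar", mask, c(10, 10, 10))  # 1 cc voxels
    doses <- round(runif(n, 0, 70), 3)
    d <- dose_grid(array(doses, c(n, 1, 1)), c(10, 10, 10))
    h <- dvh(d, sv)
    for (x in c(5, 50, 95)) {
      br <- dx_bracket(doses, x)
      got <- endpoint_Dx(h, x)
      expect_gte(got, br[1] - 1e-9); expect_lte(got, br[2] + 1e-9)
    }
    thr <- runif(1, 0, 70)
    expect_equal(endpoint_Vx(h, thr), mean(doses >= thr))
    # D_cc at an exact multiple of the voxel volume hits an order statistic
    k <- sample(1:n, 1)
    expect_equal(endpoint_D_cc(d, sv, cc = k),
                 sort(doses, decreasing = TRUE)[k])
  }
  cs <- uniform_case()
  expect_error(endpoint_D_cc(cs$d, cs$ph$T, cc = 1e6), "volume exceeds")
})

test_that("normalization rules rescale by a single exact factor", {
  cs <- uniform_case(gy = 45, presc = 50)
  nd <- normalize_dose(cs$d, cs$ph$T, "D95_100")
  expect_equal(max(abs(nd$dose - 50)), 0)
  # idempotence
  nd2 <- normalize_dose(nd, cs$ph$T, "D95_100")
  expect_equal(nd2$dose, nd$dose)
  # D97 -> 99% rule on uniform dose
  nd3 <- normalize_dose(cs$d, cs$ph$T, "D97_99")
  expect_equal(unique(as.vector(nd3$dose)), 0.99 * 50)
  zero <- cs$d; zero$dose[] <- 0
  expect_error(normalize_dose(zero, cs$ph$T), "degenerate dose")
})

test_that("Paddick CI covers the canonical configurations", {
  ph <- concentric_phantom(r_target = 10)
  # PIV == TV exactly: dose prescribed on the target mask only
  arr <- array(0, dim(ph$T$mask)); arr[ph$T$mask] <- 60
  d <- dose_grid(arr, ph$T$spacing_mm, prescription_gy = 60)
  expect_equal(ci_paddick(d, ph$T), 1.0)
  # PIV of twice the TV volume containing all of TV -> 0.5
  tv <- sum(ph$T$mask)
  arr2 <- array(0, dim(ph$T$mask))
  ord <- order(-as.vector(ph$T$mask))      # target voxels first
  arr2[ord[1:(2 * tv)]] <- 60
  d2 <- dose_grid(arr2, ph$T$spacing_mm, prescription_gy = 60)
  expect_equal(ci_paddick(d2, ph$T), tv^2 / (tv * 2 * tv))
  # disjoint PIV -> 0; empty PIV -> 0
  arr3 <- array(0, dim(ph$T$mask)); arr3[!ph$T$mask] <- 60
  arr3[ph$T$mask] <- 0
  d3 <- dose_grid(arr3, ph$T$spacing_mm, prescription_gy = 60)
  expect_equal(ci_paddick(d3, ph$T), 0)
  expect_equal(ci_paddick(dose_grid(array(0, dim(ph$T$mask)),
                                    ph$T$spacing_mm, prescription_gy = 60),
                          ph$T), 0)
})

test_that("HI95 = V95 - V105 in percent", {
  ph <- concentric_phantom(r_target = 10)
  nvox <- sum(ph$T$mask)
  arr <- array(0, dim(ph$T$mask))
  idx <- which(ph$T$mask)
  half <- idx[seq_len(floor(nvox / 2))]
  arr[half] <- 0.96 * 50
  arr[setdiff(idx, half)] <- 1.06 * 50
  d <- dose_grid(arr, ph$T$spacing_mm, prescription_gy = 50)
  # V95 = 100% (both halves above 47.5 Gy), V105 = the hot half only
  expect_equal(hi95(d, ph$T), 100 * length(half) / nvox)
  # all below 95%: HI = 0
  low <- dose_grid(array(0.9 * 50, dim(ph$T$mask)), ph$T$spacing_mm,
                   prescription_gy = 50)
  expect_equal(hi95(low, ph$T), 0)
})

test_that("CI and HI are invariant under matched dose/prescription rescaling", {
  ph <- concentric_phantom(r_target = 10)
  d <- make_dose(dose_spec("spherical-falloff", 52, falloff_radius_mm = 9,
                           gradient_pct_per_mm = 4), ph$T,
                 prescription_gy = 50)
  for (f in c(0.5, 2)) {
    ds <- d; ds$dose <- d$dose * f; ds$prescription_gy <- 50 * f
    expect_equal(ci_paddick(ds, ph$T), ci_paddick(d, ph$T))
    expect_equal(hi95(ds, ph$T), hi95(d, ph$T))
  }
})
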