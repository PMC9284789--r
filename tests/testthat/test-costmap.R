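# GT / GC cost maps and recipes

coarse_axes <- list(g = seq(0, 340, 20), t = seq(-60, 60, 20))
open_env <- patient_envelope(box_min_mm = c(-60, -60, -60),
                             box_max_mm = c(60, 60, 60),
                             ct_extent_mm = c(-1000, 1000))

test_that("combined map is the normalized weighted sum of layers", {
  ph <- make_phantom(phantom_spec(
    c(31, 31, 31), 2,
    target = list(name = "T", shape = shape_ellipsoid(c(0, 0, 0), 10)),
    oars = list(list(name = "A", shape = shape_ellipsoid(c(18, 0, 0), 6)),
                list(name = "B", shape = shape_ellipsoid(c(0, 0, 14), 5)))))
  m <- build_gt_map(ph$T, ph[c("A", "B")], weights = c(A = 1, B = 3),
                    gantry_deg = coarse_axes$g, table_deg = coarse_axes$t,
                    envelope = open_env)
  manual <- (m$layers$A * 1 + m$layers$B * 3) / 4
  expect_equal(m$combined, manual)
  # weighted-sum spot check: cells where A = 0.2, B = 0.6 combine to 0.5
  expect_equal((0.2 * 1 + 0.6 * 3) / 4, 0.5)
  # bounded by the layer envelope cellwise
  expect_true(all(m$combined >= pmin(m$layers$A, m$layers$B) - 1e-12))
  expect_true(all(m$combined <= pmax(m$layers$A, m$layers$B) + 1e-12))
})

test_that("single-OAR map equals its layer; identical layers collapse", {
  ph <- concentric_phantom()
  m <- build_gt_map(ph$T, ph["O"], gantry_deg = coarse_axes$g,
                    table_deg = coarse_axes$t, envelope = open_env)
  expect_equal(m$combined, m$layers$O)
  m2 <- build_gt_map(ph$T, list(O1 = ph$O, O2 = ph$O),
                     weights = c(O1 = 0.3, O2 = 1.7),
                     gantry_deg = coarse_axes$g, table_deg = coarse_axes$t,
                     envelope = open_env)
  expect_equal(m2$combined, m2$layers$O1)
  expect_error(build_gt_map(ph$T, list(), gantry_deg = coarse_axes$g,
                            table_deg = coarse_axes$t,
                            envelope = open_env), "empty OAR selection")
})

test_that("mirrored OAR gives the gantry/table-mirrored map", {
  # OAR large enough (~270 voxels) that one-voxel raster quantization
  # stays well under the comparison tolerance
  base <- function(x0) phantom_spec(
    c(41, 31, 31), 2,
    target = list(name = "T", shape = shape_ellipsoid(c(0, 0, 0), 10)),
    oars = list(list(name = "O", shape = shape_ellipsoid(c(x0, 0, 6), 8))))
  phR <- make_phantom(base(20)); phL <- make_phantom(base(-20))
  g <- seq(0, 315, 45); t <- seq(-45, 45, 45)
  mR <- build_gt_map(phR$T, phR["O"], gantry_deg = g, table_deg = t,
                     envelope = open_env)
  mL <- build_gt_map(phL$T, phL["O"], gantry_deg = g, table_deg = t,
                     envelope = open_env)
  # reflection x -> -x maps (gantry, table) to (-gantry mod 360, -table)
  for (i in seq_along(g)) for (j in seq_along(t)) {
    gi <- which(abs(circ_diff(g, -g[i])) < 1e-9)
    tj <- which(abs(t + t[j]) < 1e-9)
    expect_lt(abs(mL$layers$O[i, j] - mR$layers$O[gi, tj]), 0.03)
  }
})

test_that("GC width map: sphere constant, rectangle follows its extents", {
  ph <- concentric_phantom(r_target = 10)
  gc <- build_gc_map(ph$T, gantry_deg = c(0, 40, 90), table_deg = c(0, 0, 0),
                     collimator_deg = seq(-180, 150, 30))
  expect_true(all(abs(gc$width - mean(gc$width)) < 2.5))
  # rectangular 20 x 60 mm footprint from a cuboid mask
  mask <- array(FALSE, c(31, 31, 41))
  # voxel centres spanning 18 mm in x and 58 mm in z: with the one-voxel
  # footprint padding this is a 20 x 60 mm field
  mask[12:21, 15:17, 6:35] <- TRUE
  box <- structure_volume("box", "target", mask, 2)
  gcb <- build_gc_map(box, gantry_deg = 0, table_deg = 0,
                      collimator_deg = c(0, 90))
  # BEV x at collimator 0 aligns with the 20 mm side
  expect_equal(gcb$width[1, 1], 20, tolerance = 1.5)
  expect_equal(gcb$width[1, 2], 60, tolerance = 1.5)
  # 180-degree periodicity
  gcp <- build_gc_map(box, gantry_deg = 0, table_deg = 0,
                      collimator_deg = c(-150, 30, 45, -135))
  expect_equal(gcp$width[1, 1], gcp$width[1, 2], tolerance = 1e-9)
  expect_equal(gcp$width[1, 3], gcp$width[1, 4], tolerance = 1e-9)
})

test_that("path recipes resolve structures, weights and strategies", {
  ph <- make_phantom(hn_phantom_spec(spacing_mm = 4))
  rec <- weighted_recipe_from_config(
    list(oars = c("parotid_R", "parotid_L", "cord"), strategy = "SF"), ph)
  expect_named(rec$oars, c("parotid_R", "parotid_L", "cord"))
  expect_equal(unname(rec$weights), c(1, 1, 1))
  expect_equal(rec$strategy, "split-field")
  expect_equal(weighted_recipe_from_config(
    list(oars = "cord", strategy = "CRot"), ph)$strategy,
    "collimator-offset-90")
  expect_error(weighted_recipe_from_config(list(oars = character()), ph),
               "empty OAR selection")
  expect_error(weighted_recipe_from_config(
    list(oars = "oral_cavity", strategy = "SF"), ph), "unknown structure")
})
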