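# Gantry-table and collimator-gantry cost maps.

#' Build a gantry-table cost map
#'
#' For each (gantry, table) cell, one layer per OAR holds the fractional
#' target/OAR overlap in beam's eye view; layers are combined in a weighted
#' sum normalized by the sum of weights (so the combined cost stays in
#' [0, 1] and path costs are comparable across OAR recipes). Exclusion zones
#' come from the collision model and the CT-scan-length restriction and
#' carry infinite effective cost for path-finding.
#'
#' @param target target \code{\link{structure_volume}}.
#' @param oars named list of OAR \code{\link{structure_volume}}s (>= 1).
#' @param weights named or positional non-negative weights, default equal.
#' @param gantry_deg gantry axis, default \code{seq(0, 358, by = 2)}.
#' @param table_deg table axis, default \code{seq(-90, 90, by = 2)}.
#' @param clearance a \code{\link{linac_clearance}}.
#' @param envelope a \code{\link{patient_envelope}}; its CT extent defaults
#'   to the grid z-range of the target when built via
#'   \code{\link{patient_envelope}} defaults.
#' @param sad_mm source-axis distance.
#' @param depth_weights upstream/downstream OAR voxel weights passed to
#'   \code{\link{overlap_fraction}}.
#' @param res_mm BEV raster resolution.
#' @return object of class \code{gt_map}: axes, per-OAR \code{layers},
#'   \code{weights}, \code{combined}, \code{excluded}, \code{cause}.
#' @export
build_gt_map <- function(target, oars, weights = NULL,
                         gantry_deg = seq(0, 358, by = 2),
                         table_deg = seq(-90, 90, by = 2),
                         clearance = linac_clearance(),
                         envelope = patient_envelope(),
                         sad_mm = 1000, depth_weights = c(1, 0.5),
                         res_mm = 1) {
  if (length(oars) == 0) stop("empty OAR selection")
  if (is.null(names(oars)) || any(names(oars) == ""))
    names(oars) <- vapply(oars, function(o) o$name, character(1))
  if (is.null(weights)) weights <- rep(1, length(oars))
  if (is.null(names(weights))) names(weights) <- names(oars)
  stopifnot(all(weights >= 0), sum(weights) > 0)
  ng <- length(gantry_deg); nt <- length(table_deg)
  layers <- lapply(oars, function(o) matrix(0, ng, nt))
  oar_coords <- lapply(oars, voxel_coords)
  n_oar <- vapply(oar_coords, nrow, integer(1))
  wmax <- max(depth_weights)
  for (j in seq_len(nt)) for (i in seq_len(ng)) {
    geo <- beam_geometry(gantry_deg[i], table_deg[j], sad_mm)
    basis <- bev_basis(geo)
    fp <- target_footprint(target, geo, basis, res_mm = res_mm)
    for (k in seq_along(oars)) {
      pr <- project_points(oar_coords[[k]], geo, basis)
      inside <- footprint_contains(fp, pr$xy)
      w <- ifelse(pr$depth < fp$depth_median, depth_weights[1],
                  depth_weights[2])
      layers[[k]][i, j] <- if (wmax == 0) 0 else
        sum(w * inside) / (n_oar[k] * wmax)
    }
  }
  combined <- Reduce(`+`, Map(function(l, w) l * w, layers,
                              weights[names(layers)])) / sum(weights)
  ex <- exclusion_mask(gantry_deg, table_deg, clearance, envelope, target,
                       sad_mm)
  obj <- list(gantry_deg = gantry_deg, table_deg = table_deg,
              layers = layers, weights = weights, combined = combined,
              excluded = ex$excluded, cause = ex$cause, sad_mm = sad_mm)
  class(obj) <- "gt_map"
  obj
}

#' @export
print.gt_map <- function(x, ...) {
  cat(sprintf("<gt_map> %d x %d (gantry x table), %d OAR layer(s), %d excluded cells\n",
              length(x$gantry_deg), length(x$table_deg), length(x$layers),
              sum(x$excluded)))
  invisible(x)
}

#' Build a collimator-gantry field-width map along a gantry-table path
#'
#' For each control point of a chosen GT path, the cost at collimator angle
#' c is the extent (mm) of the target's BEV footprint along the leaf-travel
#' (x) direction after rotating the footprint by -c about the beam axis.
#' Following the field-width minimum reduces the leaf travel the MLC must
#' cover. Widths are 180-degree periodic in the collimator angle.
#'
#' @param target target \code{\link{structure_volume}}.
#' @param gantry_deg,table_deg equal-length vectors: the GT path.
#' @param collimator_deg collimator axis, default \code{seq(-180, 178, 2)}.
#' @param sad_mm source-axis distance.
#' @return object of class \code{gc_map}: \code{gantry_deg},
#'   \code{table_deg}, \code{collimator_deg}, and the \code{width} cost
#'   matrix (gantry x collimator), mm.
#' @export
build_gc_map <- function(target, gantry_deg, table_deg,
                         collimator_deg = seq(-180, 178, by = 2),
                         sad_mm = 1000) {
  if (!any(target$mask)) stop("empty structure")
  stopifnot(length(gantry_deg) == length(table_deg))
  coords <- voxel_coords(target)
  nc <- length(collimator_deg)
  ng <- length(gantry_deg)
  e <- rbind(cos(deg2rad(collimator_deg)), sin(deg2rad(collimator_deg)))
  width <- matrix(0, ng, nc)
  pad <- max(target$spacing_mm)  # voxel half-width on both sides
  for (i in seq_len(ng)) {
    geo <- beam_geometry(gantry_deg[i], table_deg[i], sad_mm)
    pr <- project_points(coords, geo)
    proj <- pr$xy %*% e                      # n x nc
    width[i, ] <- apply(proj, 2, max) - apply(proj, 2, min) + pad
  }
  obj <- list(gantry_deg = gantry_deg, table_deg = table_deg,
              collimator_deg = collimator_deg, width = width,
              sad_mm = sad_mm)
  class(obj) <- "gc_map"
  obj
}

#' Expand a path recipe into OAR selections, weights and duplication
#'
#' A path recipe names the OARs whose maps are combined for one GT path and
#' the duplication strategy used to turn the resulting path into one or two
#' deliverable trajectories. OAR maps are equally weighted by default.
#'
#' @param recipe list with \code{oars} (character vector of structure
#'   names), optional \code{weights}, and \code{strategy} in \code{"none"},
#'   \code{"SF"}/\code{"split-field"},
#'   \code{"CRot"}/\code{"collimator-offset-90"}.
#' @param structures named list of available \code{structure_volume}s.
#' @return list with \code{oars} (named list of structures), \code{weights},
#'   \code{strategy} (canonical name).
#' @export
weighted_recipe_from_config <- function(recipe, structures) {
  if (length(recipe$oars) == 0) stop("empty OAR selection")
  missing <- setdiff(recipe$oars, names(structures))
  if (length(missing))
    stop(sprintf("unknown structure: %s", paste(missing, collapse = ", ")))
  strat <- recipe$strategy
  if (is.null(strat)) strat <- "none"
  strat <- switch(strat,
                  "SF" = , "split-field" = "split-field",
                  "CRot" = , "collimator-offset-90" = "collimator-offset-90",
                  "none" = "none",
                  stop(sprintf("unknown duplication strategy: %s", strat)))
  w <- recipe$weights
  if (is.null(w)) w <- rep(1, length(recipe$oars))
  names(w) <- recipe$oars
  list(oars = structures[recipe$oars], weights = w, strategy = strat)
}
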