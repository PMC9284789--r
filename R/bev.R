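#' Project a structure into the beam's eye view
#'
#' Each voxel centre is projected from the point source (at \code{sad_mm}
#' upstream of the isocenter) onto the plane through the isocenter
#' perpendicular to the beam axis, i.e. a divergent projection with
#' magnification \code{sad / depth}. Depth is the signed distance from the
#' source along the beam axis, so a voxel at the isocenter has depth
#' \code{sad_mm}.
#'
#' @param structure a \code{\link{structure_volume}}.
#' @param geometry a \code{\link{beam_geometry}}.
#' @return object of class \code{bev_projection}: list with \code{xy}
#'   (n x 2 matrix, mm, collimator-unrotated BEV frame) and \code{depth_mm}.
#' @export
project_to_bev <- function(structure, geometry) {
  if (!any(structure$mask)) stop("empty structure")
  coords <- voxel_coords(structure)
  pr <- project_points(coords, geometry)
  out <- list(xy = pr$xy, depth_mm = pr$depth)
  class(out) <- "bev_projection"
  out
}

# divergent projection of an n x 3 coordinate matrix (mm, isocenter-relative)
project_points <- function(coords, geometry, basis = NULL) {
  if (is.null(basis)) basis <- bev_basis(geometry)
  sad <- geometry$sad_mm
  # source sits at -sad * d; p - source = p + sad * d
  depth <- as.numeric(coords %*% basis$d) + sad
  if (any(depth <= 0)) stop("voxel behind the source")
  scale <- sad / depth
  xy <- cbind(as.numeric(coords %*% basis$u) * scale,
              as.numeric(coords %*% basis$v) * scale)
  list(xy = xy, depth = depth)
}

# Rasterized BEV footprint of the target. Each projected voxel centre stamps
# a (2*stamp+1)^2 neighbourhood of raster cells so that a mask sampled at
# voxel spacing s still yields a filled footprint at raster resolution
# res_mm. Returns the raster (logical matrix), its cell origin and the
# median projected-target depth.
target_footprint <- function(target, geometry, basis = NULL, res_mm = 1) {
  coords <- voxel_coords(target)
  pr <- project_points(coords, geometry, basis)
  xy <- pr$xy
  stamp <- ceiling(max(target$spacing_mm) / 2 / res_mm)
  xmin <- min(xy[, 1]) - (stamp + 1) * res_mm
  ymin <- min(xy[, 2]) - (stamp + 1) * res_mm
  nx <- ceiling((max(xy[, 1]) - xmin) / res_mm) + stamp + 2
  ny <- ceiling((max(xy[, 2]) - ymin) / res_mm) + stamp + 2
  ras <- matrix(FALSE, nx, ny)
  ix <- floor((xy[, 1] - xmin) / res_mm) + 1
  iy <- floor((xy[, 2] - ymin) / res_mm) + 1
  for (dx in -stamp:stamp) for (dy in -stamp:stamp) {
    ras[cbind(ix + dx, iy + dy)] <- TRUE
  }
  list(raster = ras, xmin = xmin, ymin = ymin, res = res_mm,
       depth_median = stats::median(pr$depth))
}

# TRUE for each query point (n x 2 BEV mm) falling on a covered raster cell
footprint_contains <- function(fp, xy) {
  ix <- floor((xy[, 1] - fp$xmin) / fp$res) + 1
  iy <- floor((xy[, 2] - fp$ymin) / fp$res) + 1
  inside <- ix >= 1 & iy >= 1 & ix <= nrow(fp$raster) & iy <= ncol(fp$raster)
  out <- logical(nrow(xy))
  out[inside] <- fp$raster[cbind(ix[inside], iy[inside])]
  out
}

#' Fractional target/OAR overlap in the beam's eye view
#'
#' The geometric cost driving the gantry-table cost maps: the fraction of
#' OAR voxels whose BEV projection falls inside the target's BEV footprint,
#' weighted by the OAR voxel's position relative to the target along the
#' beam axis (an OAR proximal to the source shadows the target; a distal one
#' only receives exit dose). With both weights equal to 1 this is the plain
#' fractional volume overlap.
#'
#' @param target,oar \code{\link{structure_volume}}s on a shared grid.
#' @param geometry a \code{\link{beam_geometry}}.
#' @param weights length-2 numeric \code{c(upstream, downstream)}: weight for
#'   OAR voxels upstream (closer to the source than the target's median
#'   projected depth) and downstream of the target. Default \code{c(1, 0.5)}.
#' @param res_mm BEV raster resolution, default 1 mm.
#' @param footprint optional precomputed target footprint (internal reuse).
#' @return overlap fraction in [0, 1].
#' @export
overlap_fraction <- function(target, oar, geometry, weights = c(1, 0.5),
                             res_mm = 1, footprint = NULL) {
  if (!any(oar$mask)) stop("empty structure")
  if (!same_grid(target, oar)) stop("structures are not on a shared grid")
  stopifnot(length(weights) == 2, all(weights >= 0))
  if (is.null(footprint)) footprint <- target_footprint(target, geometry,
                                                        res_mm = res_mm)
  pr <- project_points(voxel_coords(oar), geometry)
  inside <- footprint_contains(footprint, pr$xy)
  w <- ifelse(pr$depth < footprint$depth_median, weights[1], weights[2])
  wmax <- max(weights)
  if (wmax == 0) return(0)
  sum(w * inside) / (length(w) * wmax)
}
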