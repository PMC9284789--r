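# Analytic stand-in for a virtual-linac collision model: the gantry head is
# an arc of a ring (cylindrical surface about the gantry rotation axis) of
# limited longitudinal and azimuthal extent, positioned at the current
# gantry angle; the patient + table top is an axis-aligned box in the table
# frame, sampled along its edges. A safety margin inflates both components,
# so a point collides when its radial distance reaches
# clearance - 2 * margin inside the (margin-inflated) head slab and arc.

#' Linac clearance geometry
#'
#' @param gantry_clearance_radius_mm distance from the gantry rotation axis
#'   to the closest gantry surface, default 400.
#' @param gantry_slab_halfwidth_mm longitudinal half-extent of the gantry
#'   head path about the gantry plane, default 300.
#' @param head_arc_halfangle_deg azimuthal half-extent of the gantry head
#'   about the gantry angle, default 30.
#' @param safety_margin_mm margin applied to each component, default 20
#'   (2 cm).
#' @param sad_mm source-axis distance, default 1000.
#' @return object of class \code{linac_clearance}.
#' @export
linac_clearance <- function(gantry_clearance_radius_mm = 400,
                            gantry_slab_halfwidth_mm = 300,
                            head_arc_halfangle_deg = 30,
                            safety_margin_mm = 20, sad_mm = 1000) {
  stopifnot(gantry_clearance_radius_mm > 0, gantry_slab_halfwidth_mm > 0,
            head_arc_halfangle_deg > 0, safety_margin_mm >= 0, sad_mm > 0)
  obj <- list(radius = gantry_clearance_radius_mm,
              slab = gantry_slab_halfwidth_mm,
              head_arc = head_arc_halfangle_deg,
              margin = safety_margin_mm, sad = sad_mm)
  class(obj) <- "linac_clearance"
  obj
}

#' Patient + table envelope
#'
#' Axis-aligned bounding box of the patient and table top in the table frame
#' (same axes as the patient frame at table 0). The default is a plausible
#' supine head-first setup: a 50 cm-wide table extending 90 cm inferior of
#' the isocenter, patient surface within 12 cm anterior / 18 cm posterior
#' (table top included).
#'
#' @param box_min_mm,box_max_mm length-3 corners of the box, mm.
#' @param headrest_ref_mm reference point on the headrest (superior box end).
#' @param ct_extent_mm length-2 inferior/superior CT-scan limits, mm.
#' @param body_xy_halfwidth_mm length-2 half-extents (x, y) of the patient
#'   body cross-section around the isocenter axis, used by the
#'   CT-scan-length restriction (the table does not contain un-scanned
#'   anatomy, so it is excluded from that test). Default c(100, 120).
#' @param edge_sample_mm sampling step along box edges, default 10.
#' @return object of class \code{patient_envelope}.
#' @export
patient_envelope <- function(box_min_mm = c(-250, -180, -900),
                             box_max_mm = c(250, 120, 150),
                             headrest_ref_mm = NULL,
                             ct_extent_mm = c(-160, 160),
                             body_xy_halfwidth_mm = c(100, 120),
                             edge_sample_mm = 10) {
  stopifnot(all(box_max_mm > box_min_mm), ct_extent_mm[2] > ct_extent_mm[1],
            all(body_xy_halfwidth_mm > 0))
  if (is.null(headrest_ref_mm))
    headrest_ref_mm <- c(0, 0, box_max_mm[3])
  obj <- list(box_min = as.numeric(box_min_mm),
              box_max = as.numeric(box_max_mm),
              headrest_ref = as.numeric(headrest_ref_mm),
              ct_extent = as.numeric(ct_extent_mm),
              body_xy = as.numeric(body_xy_halfwidth_mm),
              edge_sample = edge_sample_mm)
  class(obj) <- "patient_envelope"
  obj
}

# sample points on the 12 edges of the envelope box (n x 3, table frame)
envelope_edge_points <- function(envelope) {
  lo <- envelope$box_min; hi <- envelope$box_max
  step <- envelope$edge_sample
  pts <- list()
  for (ax in 1:3) {
    s <- seq(lo[ax], hi[ax], by = step)
    if (s[length(s)] != hi[ax]) s <- c(s, hi[ax])
    others <- setdiff(1:3, ax)
    for (a in c(lo[others[1]], hi[others[1]]))
      for (b in c(lo[others[2]], hi[others[2]])) {
        m <- matrix(0, length(s), 3)
        m[, ax] <- s; m[, others[1]] <- a; m[, others[2]] <- b
        pts[[length(pts) + 1]] <- m
      }
  }
  unique(do.call(rbind, pts))
}

# envelope points rotated into the room by the table angle (rotation about
# the vertical y axis through the isocenter)
rotated_envelope_points <- function(envelope, table_deg) {
  envelope_edge_points(envelope) %*% t(rot_y(-table_deg))
}

#' Gantry-table collision test
#'
#' TRUE when any sampled envelope point, after table rotation, comes within
#' the (mutually margin-inflated) clearance of the gantry head at its
#' current position: radial distance from the gantry axis at least
#' \code{radius - 2 * margin}, longitudinally within \code{slab + margin}
#' of the gantry plane, and azimuthally within the head arc about the
#' gantry angle.
#'
#' @param geometry a \code{\link{beam_geometry}}.
#' @param clearance a \code{\link{linac_clearance}}.
#' @param envelope a \code{\link{patient_envelope}}.
#' @param points optional precomputed rotated envelope points.
#' @return logical.
#' @export
collides <- function(geometry, clearance, envelope, points = NULL) {
  if (is.null(points)) points <- rotated_envelope_points(envelope,
                                                         geometry$table_deg)
  r <- sqrt(points[, 1]^2 + points[, 2]^2)
  in_slab <- abs(points[, 3]) <= clearance$slab + clearance$margin
  # azimuth 0 at +y (gantry 0, anterior), increasing with gantry angle
  az <- atan2(points[, 1], points[, 2]) * 180 / pi
  in_arc <- abs(circ_diff(az, geometry$gantry_deg)) <= clearance$head_arc
  any(in_slab & in_arc & r >= clearance$radius - 2 * clearance$margin)
}

#' CT-scan-length exclusion test
#'
#' TRUE when the divergent beam subtending the target would irradiate
#' through anatomy beyond the scanned CT range: any ray from the source to a
#' corner of the target's bounding box crosses the inferior or superior CT
#' boundary plane at a point still inside the patient body cross-section
#' (\code{body_xy_halfwidth_mm} of the envelope).
#'
#' @param geometry a \code{\link{beam_geometry}}.
#' @param envelope a \code{\link{patient_envelope}} (supplies
#'   \code{ct_extent_mm} and the body cross-section).
#' @param target target \code{\link{structure_volume}}.
#' @return logical.
#' @export
ct_length_exclusion <- function(geometry, envelope, target) {
  d <- beam_direction(geometry)
  src <- -geometry$sad_mm * d
  bb <- apply(voxel_coords(target), 2, range)
  corners <- as.matrix(expand.grid(bb[, 1], bb[, 2], bb[, 3]))
  # beam direction already lives in the patient frame, so the body
  # cross-section (envelope x/y box) is used un-rotated
  for (zb in envelope$ct_extent) {
    for (i in seq_len(nrow(corners))) {
      dir <- corners[i, ] - src
      if (abs(dir[3]) < 1e-12) next
      t_hit <- (zb - src[3]) / dir[3]
      if (t_hit <= 0) next
      hit <- src + t_hit * dir
      if (abs(hit[1]) <= envelope$body_xy[1] + 1e-9 &&
          abs(hit[2]) <= envelope$body_xy[2] + 1e-9)
        return(TRUE)
    }
  }
  FALSE
}

#' Exclusion mask over a gantry-table grid
#'
#' Cellwise OR of \code{\link{collides}} and
#' \code{\link{ct_length_exclusion}}, with the cause retained for plotting
#' (mirroring the usual light-grey collision / dark-grey end-of-CT shading
#' of GT maps).
#'
#' @param gantry_deg,table_deg axis vectors of the GT grid, degrees.
#' @param clearance a \code{\link{linac_clearance}}.
#' @param envelope a \code{\link{patient_envelope}}.
#' @param target target \code{\link{structure_volume}}.
#' @param sad_mm source-axis distance.
#' @return list with logical matrix \code{excluded} (gantry x table) and
#'   character matrix \code{cause} ("", "collision", "ct", "both").
#' @export
exclusion_mask <- function(gantry_deg, table_deg, clearance, envelope,
                           target, sad_mm = 1000) {
  ng <- length(gantry_deg); nt <- length(table_deg)
  excl <- matrix(FALSE, ng, nt)
  cause <- matrix("", ng, nt)
  for (j in seq_len(nt)) {
    pts <- rotated_envelope_points(envelope, table_deg[j])
    for (i in seq_len(ng)) {
      geo <- beam_geometry(gantry_deg[i], table_deg[j], sad_mm)
      col_ij <- collides(geo, clearance, envelope, points = pts)
      ct <- ct_length_exclusion(geo, envelope, target)
      excl[i, j] <- col_ij || ct
      cause[i, j] <- if (col_ij && ct) "both" else if (col_ij) "collision"
        else if (ct) "ct" else ""
    }
  }
  list(excluded = excl, cause = cause)
}
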