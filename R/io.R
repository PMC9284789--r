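# Readers/writers: ASCII NRRD volumes with a JSON sidecar, trajectory
# tables (CSV/JSON), delivery-log CSV, and the JSON run configuration.

#' Write a volume as ASCII NRRD
#'
#' Minimal NRRD0004 writer using \code{encoding: ascii} (text-only files).
#' Masks are written as 0/1 integers, dose as doubles. Spacing and origin
#' (mm) are stored in the header.
#'
#' @param x a \code{\link{structure_volume}} or \code{\link{dose_grid}}.
#' @param path output file path (.nrrd).
#' @return the path, invisibly.
#' @export
write_nrrd <- function(x, path) {
  if (inherits(x, "structure_volume")) {
    a <- x$mask + 0L; type <- "int"
  } else if (inherits(x, "dose_grid")) {
    a <- x$dose; type <- "double"
  } else stop("unsupported object")
  dm <- dim(a)
  hdr <- c("NRRD0004",
           sprintf("type: %s", type),
           "dimension: 3",
           sprintf("sizes: %d %d %d", dm[1], dm[2], dm[3]),
           sprintf("spacings: %.9g %.9g %.9g", x$spacing_mm[1],
                   x$spacing_mm[2], x$spacing_mm[3]),
           "space: left-posterior-superior",
           sprintf("space origin: (%.9g,%.9g,%.9g)", x$origin_mm[1],
                   x$origin_mm[2], x$origin_mm[3]),
           "encoding: ascii",
           "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  # column-major order, 8 values per line to keep lines short
  v <- as.vector(a)
  chunks <- split(v, ceiling(seq_along(v) / 8))
  writeLines(vapply(chunks, function(ch)
    paste(format(ch, trim = TRUE, scientific = FALSE, digits = 12),
          collapse = " "), character(1)), con)
  invisible(path)
}

#' Read an ASCII NRRD volume
#'
#' @param path file path.
#' @return list with \code{data} (numeric 3D array), \code{spacing_mm},
#'   \code{origin_mm}.
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "NRRD")) stop("not an NRRD file")
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop("malformed NRRD: no header terminator")
  hdr <- lines[2:(blank - 1)]
  field <- function(name) {
    ln <- grep(paste0("^", name, ": "), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^", name, ": "), "", ln[1])
  }
  enc <- field("encoding")
  if (!identical(enc, "ascii")) stop("only ascii encoding supported")
  sizes <- as.integer(strsplit(field("sizes"), " +")[[1]])
  spacing <- as.numeric(strsplit(field("spacings"), " +")[[1]])
  org <- field("space origin")
  origin <- if (is.null(org)) rep(0, 3) else
    as.numeric(strsplit(gsub("[()]", "", org), ",")[[1]])
  vals <- as.numeric(unlist(strsplit(lines[(blank + 1):length(lines)], " +")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(sizes)) stop("malformed NRRD: value count")
  list(data = array(vals, sizes), spacing_mm = spacing, origin_mm = origin)
}

#' Write a structure set (masks + JSON sidecar)
#'
#' One NRRD per structure plus \code{structures.json} recording names,
#' roles, spacing, origin and isocenter.
#'
#' @param structures named list of \code{\link{structure_volume}}s.
#' @param dir output directory (created if needed).
#' @return the sidecar path, invisibly.
#' @export
write_structure_set <- function(structures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(structures, function(s) {
    f <- paste0(gsub("[^A-Za-z0-9_.-]", "_", s$name), ".nrrd")
    write_nrrd(s, file.path(dir, f))
    list(name = s$name, role = s$role, file = f,
         spacing_mm = s$spacing_mm, origin_mm = s$origin_mm,
         isocenter_mm = s$isocenter_mm)
  })
  side <- file.path(dir, "structures.json")
  jsonlite::write_json(unname(entries), side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a structure set written by \code{\link{write_structure_set}}
#'
#' @param dir directory containing \code{structures.json}.
#' @return named list of \code{\link{structure_volume}}s.
#' @export
read_structure_set <- function(dir) {
  side <- file.path(dir, "structures.json")
  if (!file.exists(side)) stop("no structures.json sidecar in ", dir)
  entries <- jsonlite::read_json(side, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  out <- list()
  for (e in entries) {
    if (is.null(e$role)) stop("missing role tag for ", e$name)
    v <- read_nrrd(file.path(dir, e$file))
    out[[e$name]] <- structure_volume(
      e$name, e$role, v$data != 0, unlist(e$spacing_mm),
      unlist(e$origin_mm), unlist(e$isocenter_mm))
  }
  out
}

#' Write a trajectory as a control-point table
#'
#' CSV (\code{index, gantry_deg, table_deg, collimator_deg, jaw_x1_mm,
#' jaw_x2_mm}) plus a JSON twin carrying the metadata.
#'
#' @param path a \code{\link{trajectory_path}}.
#' @param file output CSV path (the JSON twin replaces the extension).
#' @return the CSV path, invisibly.
#' @export
write_trajectory <- function(path, file) {
  utils::write.csv(path$control_points, file, row.names = FALSE)
  jfile <- sub("\\.csv$", ".json", file)
  jsonlite::write_json(list(recipe = path$recipe,
                            duplication = path$duplication,
                            control_points = path$control_points),
                       jfile, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(file)
}

#' Read a trajectory control-point table (CSV)
#'
#' @param file CSV written by \code{\link{write_trajectory}}.
#' @return a \code{\link{trajectory_path}}.
#' @export
read_trajectory <- function(file) {
  cp <- utils::read.csv(file)
  meta <- list(recipe = "path", duplication = "none")
  jfile <- sub("\\.csv$", ".json", file)
  if (file.exists(jfile)) {
    j <- jsonlite::read_json(jfile, simplifyVector = TRUE)
    meta$recipe <- j$recipe; meta$duplication <- j$duplication
  }
  trajectory_path(cp$gantry_deg, cp$table_deg, cp$collimator_deg,
                  cp$jaw_x1_mm, cp$jaw_x2_mm, recipe = meta$recipe,
                  duplication = meta$duplication)
}

#' Write / read a delivery log (CSV schema)
#'
#' One row per control point: \code{time_s} plus
#' \code{<axis>_expected}/\code{<axis>_actual} columns.
#'
#' @param log a \code{delivery_log} data frame.
#' @param file CSV path.
#' @return the path (write) or the log (read).
#' @export
write_delivery_log <- function(log, file) {
  utils::write.csv(as.data.frame(log), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_delivery_log
#' @export
read_delivery_log <- function(file) {
  log <- utils::read.csv(file)
  if (!"time_s" %in% names(log)) stop("invalid log")
  class(log) <- c("delivery_log", "data.frame")
  log
}

#' Default run configuration
#'
#' Central defaults for the whole pipeline; the stated machine-protocol
#' values (2 degree control-point spacing, gradient limit 3 deg/deg,
#' 10-point smoothing window, 2 cm collision safety margin, 2%/2 mm gamma
#' with 10% threshold) are the defaults here and everywhere else.
#'
#' @param ... overrides of the default fields.
#' @return a named list (class \code{run_config}).
#' @export
default_run_config <- function(...) {
  cfg <- list(
    case = "synthetic",
    gantry_step_deg = 2,
    table_step_deg = 2,
    collimator_step_deg = 2,
    gradient_limit_deg_per_deg = 3,
    smoothing_window_points = 10,
    safety_margin_mm = 20,
    sad_mm = 1000,
    split_field_overlap_mm = 5,
    gamma = list(dose_tolerance_pct = 2, dta_mm = 2,
                 low_dose_threshold_pct = 10),
    normalization_rule = "D95_100",
    recipes = list(),
    seed = 1
  )
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read a run configuration from JSON
#'
#' Unspecified fields fall back to \code{\link{default_run_config}}.
#'
#' @param file JSON config path.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  do.call(default_run_config, j)
}

#' Render a GT map as a heatmap
#'
#' Combined cost as a heat image with excluded zones shaded grey (light for
#' collisions, dark for end-of-CT restrictions), optionally overlaying a
#' path.
#'
#' @param map a \code{gt_map}.
#' @param path optional \code{gt_path} or table-angle sequence to overlay.
#' @param ... passed to \code{image}.
#' @return invisibly, NULL.
#' @export
plot_gt_map <- function(map, path = NULL, ...) {
  z <- map$combined
  graphics::image(map$gantry_deg, map$table_deg, z,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "gantry [deg]", ylab = "table [deg]", ...)
  if (any(map$excluded)) {
    idx <- which(map$excluded, arr.ind = TRUE)
    cols <- ifelse(map$cause[map$excluded] == "ct", "grey25", "grey75")
    graphics::points(map$gantry_deg[idx[, 1]], map$table_deg[idx[, 2]],
                     pch = 15, col = cols, cex = 0.5)
  }
  if (!is.null(path)) {
    tb <- if (inherits(path, "gt_path")) path$table_deg else path
    graphics::lines(map$gantry_deg, tb, col = "red", lwd = 2)
  }
  invisible(NULL)
}
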