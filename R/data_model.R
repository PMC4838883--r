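#' lakemorph: annual lake-telemetry analysis of sympatric fish ecomorphs
#'
#' Pipeline components: synthetic lake and fish generators, position quality
#' control, solar/photoperiod categorisation, habitat selectivity (Jacobs D),
#' kernel home ranges clipped to the lake boundary, movement metrics in body
#' lengths per second, and stepwise discriminant morphometrics.
#'
#' @keywords internal
"_PACKAGE"

# ---- position fixes ---------------------------------------------------------

#' Construct a validated table of position fixes
#'
#' A position fix is one telemetry-derived 3-D location of one fish at one
#' instant: planar coordinates in a local metre frame, the tag's pressure
#' (depth) reading, and a unitless positional-error metric where larger
#' values indicate a worse expected positioning error.
#'
#' @param fish_id character vector of fish identifiers.
#' @param t POSIXct timestamps (UTC).
#' @param x,y numeric coordinates in metres (local planar frame).
#' @param tag_depth numeric tag depth in metres below surface (>= 0).
#' @param err numeric positional-error metric (>= 0).
#' @param valid logical QC flag, defaults to `TRUE`.
#' @return A `data.frame` sorted by `(fish_id, t)` with the six columns above.
#' @export
position_fixes <- function(fish_id, t, x, y, tag_depth, err,
                           valid = TRUE) {
  stopifnot(inherits(t, "POSIXct"))
  df <- data.frame(
    fish_id = as.character(fish_id), t = t,
    x = as.numeric(x), y = as.numeric(y),
    tag_depth = as.numeric(tag_depth), err = as.numeric(err),
    valid = rep_len(as.logical(valid), length(fish_id)),
    stringsAsFactors = FALSE
  )
  if (any(df$tag_depth < 0, na.rm = TRUE))
    stop("tag_depth must be >= 0")
  if (any(df$err < 0, na.rm = TRUE))
    stop("err must be >= 0")
  df <- df[order(df$fish_id, df$t), , drop = FALSE]
  dup <- duplicated(df[, c("fish_id", "t")])
  if (any(dup)) {
    first <- which(dup)[1]
    stop(sprintf("duplicate (fish_id, t) row: fish %s at %s",
                 df$fish_id[first], format(df$t[first], tz = "UTC")))
  }
  rownames(df) <- NULL
  df
}

#' Read position fixes from a delimited file
#'
#' Expects a header row; timestamps must be ISO-8601 and are read as UTC.
#' Rows failing validation (negative depth or error metric, unparsable
#' timestamp) are rejected and counted; duplicated `(fish_id, t)` rows are
#' an error.
#'
#' @param path file path to a CSV file.
#' @param dialect optional named character vector mapping the canonical
#'   column names `fish_id,timestamp,x,y,tag_depth,err` to the file's
#'   column names.
#' @return A list with elements `fixes` (see [position_fixes()]) and
#'   `n_rejected` plus `rejected_lines` (1-based data line numbers).
#' @export
read_positions <- function(path, dialect = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  canon <- c("fish_id", "timestamp", "x", "y", "tag_depth", "err")
  if (!is.null(dialect)) {
    for (nm in names(dialect)) {
      hit <- match(dialect[[nm]], names(raw))
      if (!is.na(hit)) names(raw)[hit] <- nm
    }
  }
  missing_cols <- setdiff(canon, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  t <- as.POSIXct(raw$timestamp, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                 "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  bad_time <- is.na(t)
  bad_depth <- !is.na(raw$tag_depth) & raw$tag_depth < 0
  bad_err <- !is.na(raw$err) & raw$err < 0
  bad <- bad_time | bad_depth | bad_err | is.na(raw$tag_depth) | is.na(raw$err)
  if (any(bad_time))
    warning(sprintf("%d row(s) with unparsable timestamp (first at data line %d)",
                    sum(bad_time), which(bad_time)[1]))
  keep <- !bad
  fixes <- position_fixes(raw$fish_id[keep], t[keep], raw$x[keep], raw$y[keep],
                          raw$tag_depth[keep], raw$err[keep])
  list(fixes = fixes, n_rejected = sum(bad), rejected_lines = which(bad))
}

#' Write position fixes to CSV
#'
#' Timestamps are written as ISO-8601 UTC; a write/read round trip
#' reproduces values exactly for finite inputs.
#'
#' @param fixes a position-fix table.
#' @param path output file path.
#' @export
write_positions <- function(fixes, path) {
  out <- data.frame(
    fish_id = fixes$fish_id,
    timestamp = format(fixes$t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    x = fixes$x, y = fixes$y, tag_depth = fixes$tag_depth, err = fixes$err,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- bathymetry grid --------------------------------------------------------

#' Construct a bathymetry grid
#'
#' Depths are metres of water, positive down; `NA` cells are land. The grid
#' origin `(x0, y0)` is the lower-left corner; row 1 of the depth matrix is
#' the southernmost (y-min) row and cell `(i, j)` covers the half-open
#' square `[x0+(j-1)s, x0+js) x [y0+(i-1)s, y0+is)`.
#'
#' @param x0,y0 lower-left corner, metres.
#' @param cell_size cell edge, metres (> 0; cells are square).
#' @param depth numeric matrix of depths (rows = y, cols = x).
#' @return An object of class `bathy_grid`.
#' @export
bathy_grid <- function(x0, y0, cell_size, depth) {
  stopifnot(is.matrix(depth), cell_size > 0)
  if (all(is.na(depth))) stop("all-missing bathymetry grid")
  if (any(depth < 0, na.rm = TRUE)) stop("depths must be >= 0 (positive down)")
  structure(list(x0 = x0, y0 = y0, cell_size = cell_size, depth = depth),
            class = "bathy_grid")
}

#' @export
print.bathy_grid <- function(x, ...) {
  wet <- sum(!is.na(x$depth))
  cat(sprintf("bathy_grid: %d x %d cells of %g m, %d wet, max depth %.2f m\n",
              nrow(x$depth), ncol(x$depth), x$cell_size, wet,
              max(x$depth, na.rm = TRUE)))
  invisible(x)
}

#' Read a bathymetry grid from an ESRI ASCII grid file
#'
#' Supports the `ncols/nrows/xllcorner/yllcorner/cellsize/nodata_value`
#' header dialect. The file stores rows north-to-south; they are flipped so
#' that row 1 of the in-memory matrix is the y-min row.
#'
#' @param path file path.
#' @return A [bathy_grid()].
#' @export
read_bathymetry <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII grid header (need ", paste(need, collapse = ", "), ")")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop(sprintf("grid body has %d values, header implies %d",
                 length(vals), hdr$ncols * hdr$nrows))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # row 1 -> y-min
  bathy_grid(hdr$xllcorner, hdr$yllcorner, hdr$cellsize, m)
}

#' Write a bathymetry grid as ESRI ASCII
#'
#' @param grid a [bathy_grid()].
#' @param path output file path.
#' @param nodata value written for missing (land) cells.
#' @export
write_bathymetry <- function(grid, path, nodata = -9999) {
  m <- grid$depth[rev(seq_len(nrow(grid$depth))), , drop = FALSE]
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", format(grid$x0, digits = 15)),
    paste("yllcorner", format(grid$y0, digits = 15)),
    paste("cellsize", format(grid$cell_size, digits = 15)),
    paste("nodata_value", nodata)
  ), con)
  utils::write.table(format(m, digits = 15, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Look up water depth at planar coordinates
#'
#' Nearest-cell lookup under the half-open indexing convention
#' `[x0 + (j-1)s, x0 + js)`. Points outside the grid or over land return
#' `NA`.
#'
#' @param grid a [bathy_grid()].
#' @param x,y numeric vectors of coordinates, metres.
#' @return Numeric vector of depths (m), `NA` where undefined.
#' @export
depth_at <- function(grid, x, y) {
  j <- floor((x - grid$x0) / grid$cell_size) + 1L
  i <- floor((y - grid$y0) / grid$cell_size) + 1L
  ok <- i >= 1L & i <= nrow(grid$depth) & j >= 1L & j <= ncol(grid$depth)
  out <- rep(NA_real_, length(x))
  out[ok] <- grid$depth[cbind(i[ok], j[ok])]
  out
}

# ---- lake polygon -----------------------------------------------------------

#' Construct a lake boundary polygon
#'
#' The exterior ring of the feasible (wet) area, in the local metre frame.
#' The ring is stored open (last vertex not repeated) and must be simple.
#'
#' @param xy two-column numeric matrix of vertices (x, y), metres.
#' @return An object of class `lake_polygon`.
#' @export
lake_polygon <- function(xy) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, nrow(xy) >= 3)
  if (isTRUE(all.equal(xy[1, ], xy[nrow(xy), ])))
    xy <- xy[-nrow(xy), , drop = FALSE]
  a <- polygon_area(xy)
  if (a <= 0) stop("polygon must have positive area (counter-clockwise ring)")
  structure(list(xy = xy, area = a), class = "lake_polygon")
}

#' Signed shoelace area of a ring
#' @param xy two-column matrix of vertices, open ring.
#' @return Area in square metres (positive for counter-clockwise rings).
#' @export
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Boundary-inclusive point-in-polygon test
#'
#' Vectorised ray casting with an explicit on-boundary rule: points lying
#' exactly on an edge or vertex (within `eps`) count as inside.
#'
#' @param poly a [lake_polygon()].
#' @param x,y numeric coordinate vectors.
#' @param eps boundary snap tolerance, metres.
#' @return Logical vector.
#' @export
point_in_polygon <- function(poly, x, y, eps = 1e-9) {
  v <- poly$xy
  n <- nrow(v)
  px <- v[, 1]; py <- v[, 2]
  qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    x1 <- px[k]; y1 <- py[k]; x2 <- qx[k]; y2 <- qy[k]
    # crossing test (half-open in y avoids double-counting at vertices)
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    # distance from point to segment
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    tt <- if (L2 > 0) pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / L2)) else 0
    d2 <- (x - (x1 + tt * dx))^2 + (y - (y1 + tt * dy))^2
    on_edge <- on_edge | d2 <= eps^2
  }
  inside | on_edge
}

#' Read a lake polygon from GeoJSON
#' @param path file path to a GeoJSON Polygon (or a Feature wrapping one).
#' @return A [lake_polygon()].
#' @export
read_lake_polygon <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- if (!is.null(g$geometry)) g$geometry else g
  if (!identical(geom$type, "Polygon"))
    stop("expected a GeoJSON Polygon, got ", geom$type)
  ring <- geom$coordinates
  if (is.list(ring)) ring <- ring[[1]]
  if (length(dim(ring)) == 3) ring <- ring[1, , ]
  lake_polygon(ring)
}

#' Write a lake polygon as GeoJSON
#' @param poly a [lake_polygon()].
#' @param path output file path.
#' @export
write_lake_polygon <- function(poly, path) {
  ring <- rbind(poly$xy, poly$xy[1, ])
  obj <- list(type = "Polygon",
              coordinates = list(lapply(seq_len(nrow(ring)),
                                        function(i) ring[i, ])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- fish / trait / isotope records ----------------------------------------

#' Construct a fish metadata table
#'
#' @param fish_id identifiers.
#' @param morph one of `"Littoral"`, `"Pelagic"`, `"DwarfMaturing"`,
#'   `"Other"`.
#' @param fork_length fork length, mm (> 0).
#' @param body_mass body mass, g.
#' @param tag_mass transmitter mass, g.
#' @return A `data.frame` with a `tag_burden_pct` column
#'   (100 * tag_mass / body_mass).
#' @export
fish_records <- function(fish_id, morph, fork_length, body_mass, tag_mass) {
  morphs <- c("Littoral", "Pelagic", "DwarfMaturing", "Other")
  morph <- as.character(morph)
  if (!all(morph %in% morphs))
    stop("morph must be one of: ", paste(morphs, collapse = ", "))
  if (any(fork_length <= 0)) stop("fork_length must be > 0")
  data.frame(fish_id = as.character(fish_id), morph = morph,
             fork_length = fork_length, body_mass = body_mass,
             tag_mass = tag_mass,
             tag_burden_pct = 100 * tag_mass / body_mass,
             stringsAsFactors = FALSE)
}

#' Construct a morphometric trait table
#'
#' Each record carries fork length plus exactly nine named linear
#' measurements (mm), typically head length (HL), pelvic fin length (PEL),
#' head depth at eye (HDE), eye diameter (ED), head depth at operculum
#' (HDO) and four further body measurements.
#'
#' @param fish_id identifiers.
#' @param fork_length fork length, mm.
#' @param traits data.frame or matrix of 9 named trait columns, all > 0.
#' @return A `data.frame` with `fish_id`, `fork_length` and the traits.
#' @export
morphometric_records <- function(fish_id, fork_length, traits) {
  traits <- as.data.frame(traits)
  if (ncol(traits) != 9)
    stop("exactly 9 trait columns required, got ", ncol(traits))
  if (any(as.matrix(traits) <= 0)) stop("all traits must be > 0")
  cbind(data.frame(fish_id = as.character(fish_id),
                   fork_length = fork_length, stringsAsFactors = FALSE),
        traits)
}

#' Pipeline configuration defaults
#'
#' Collects the constants used across the pipeline: the littoral depth
#' limit (m), density-grid cell area (m^2), the home-range subsample size,
#' the kernel isopleth probabilities, the 3-hour diel blocking, QC
#' thresholds and the seed.
#'
#' @param littoral_depth_limit littoral/offshore depth cut, m.
#' @param grid_cell_area density-grid cell area, m^2 (cells are square).
#' @param homerange_sample_n positions subsampled per fish-month.
#' @param kde_isopleths utilization-distribution isopleth probabilities.
#' @param time_block_hours diel block width, hours.
#' @param error_metric_max QC threshold on the positional-error metric.
#' @param depth_concordance_tol tag-vs-bathymetry depth tolerance, m.
#' @param gap_max_intervals displacement steps spanning more than this many
#'   nominal transmission intervals are skipped.
#' @param twilight_window_min dawn/dusk half-window around sunrise/sunset,
#'   minutes.
#' @param utc_offset_hours local civil time offset from UTC, hours.
#' @param rng_seed integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(littoral_depth_limit = 8,
                            grid_cell_area = 25,
                            homerange_sample_n = 54,
                            kde_isopleths = c(0.50, 0.95),
                            time_block_hours = 3,
                            error_metric_max = 2.5,
                            depth_concordance_tol = 1,
                            gap_max_intervals = 4,
                            twilight_window_min = 60,
                            utc_offset_hours = 1,
                            rng_seed = 1L) {
  stopifnot(all(kde_isopleths > 0 & kde_isopleths < 1),
            homerange_sample_n >= 1)
  structure(list(littoral_depth_limit = littoral_depth_limit,
                 grid_cell_area = grid_cell_area,
                 homerange_sample_n = homerange_sample_n,
                 kde_isopleths = kde_isopleths,
                 time_block_hours = time_block_hours,
                 error_metric_max = error_metric_max,
                 depth_concordance_tol = depth_concordance_tol,
                 gap_max_intervals = gap_max_intervals,
                 twilight_window_min = twilight_window_min,
                 utc_offset_hours = utc_offset_hours,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}
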