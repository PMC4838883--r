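# Pre-treatment of raw positioning-system fixes: three filters applied in
# order (logger geometry quality, position inside the feasible boundary,
# tag-depth vs bathymetric-depth concordance), each fix counted once at its
# first failing filter.

#' Filter fixes on the positional-error (geometry) metric
#'
#' Drops fixes whose error metric exceeds `err_max`; larger values of the
#' metric indicate worse logger geometry at the fix.
#'
#' @param fixes position-fix table.
#' @param err_max threshold; fixes kept iff `err <= err_max`.
#' @return list(kept, removed), both in input order.
#' @export
filter_geometry <- function(fixes, err_max) {
  if (any(is.na(fixes$err))) stop("err metric missing on some fixes")
  keep <- fixes$err <= err_max
  list(kept = fixes[keep, , drop = FALSE],
       removed = fixes[!keep, , drop = FALSE])
}

#' Filter fixes to those inside the lake boundary
#'
#' Boundary-inclusive: points on an edge or vertex are kept.
#'
#' @param fixes position-fix table.
#' @param polygon a [lake_polygon()].
#' @return list(kept, removed).
#' @export
filter_inside_lake <- function(fixes, polygon) {
  if (!inherits(polygon, "lake_polygon") || polygon$area <= 0)
    stop("degenerate lake polygon")
  keep <- point_in_polygon(polygon, fixes$x, fixes$y)
  list(kept = fixes[keep, , drop = FALSE],
       removed = fixes[!keep, , drop = FALSE])
}

#' Filter fixes on tag-depth / bathymetric-depth concordance
#'
#' A fix is kept iff its tag depth does not exceed the bathymetric depth at
#' the fix by more than `tol` metres; fixes over missing bathymetry are
#' removed.
#'
#' @param fixes position-fix table.
#' @param bathy a [bathy_grid()].
#' @param tol concordance tolerance, m (>= 0).
#' @return list(kept, removed).
#' @export
filter_depth_concordance <- function(fixes, bathy, tol) {
  if (tol < 0) stop("tol must be >= 0")
  bed <- depth_at(bathy, fixes$x, fixes$y)
  keep <- !is.na(bed) & fixes$tag_depth <= bed + tol
  list(kept = fixes[keep, , drop = FALSE],
       removed = fixes[!keep, , drop = FALSE])
}

#' Run the full position quality-control pipeline
#'
#' Applies, in order: geometry filter, inside-lake filter, depth
#' concordance. Each fix is excluded once, at the first failing filter, so
#' counts conserve exactly. The headline exclusion percentage is expressed
#' relative to the retained (valid) count.
#'
#' @param fixes position-fix table.
#' @param polygon a [lake_polygon()].
#' @param bathy a [bathy_grid()].
#' @param config a [pipeline_config()] (uses `error_metric_max`,
#'   `depth_concordance_tol`).
#' @return list(valid = kept fixes, report = qc_report).
#' @export
run_qc <- function(fixes, polygon, bathy, config = pipeline_config()) {
  n_input <- nrow(fixes)
  g <- filter_geometry(fixes, config$error_metric_max)
  v <- filter_inside_lake(g$kept, polygon)
  d <- filter_depth_concordance(v$kept, bathy, config$depth_concordance_tol)
  report <- qc_report(n_input,
                      n_excluded_geometry = nrow(g$removed),
                      n_excluded_outside = nrow(v$removed),
                      n_excluded_depth = nrow(d$removed))
  d$kept$valid <- rep(TRUE, nrow(d$kept))
  list(valid = d$kept, report = report)
}

#' Build a QC accounting report
#'
#' @param n_input fixes in.
#' @param n_excluded_geometry,n_excluded_outside,n_excluded_depth per-filter
#'   exclusion counts.
#' @return list of class `qc_report` with `n_valid` and
#'   `excluded_over_valid_pct` (100 * excluded / valid; `NA` and flagged if
#'   nothing was retained).
#' @export
qc_report <- function(n_input, n_excluded_geometry, n_excluded_outside,
                      n_excluded_depth) {
  excl <- n_excluded_geometry + n_excluded_outside + n_excluded_depth
  n_valid <- n_input - excl
  pct <- if (n_valid > 0) 100 * excl / n_valid else NA_real_
  structure(list(n_input = n_input,
                 n_excluded_geometry = n_excluded_geometry,
                 n_excluded_outside = n_excluded_outside,
                 n_excluded_depth = n_excluded_depth,
                 n_valid = n_valid,
                 excluded_over_valid_pct = pct,
                 undefined_pct = n_valid == 0),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "QC: %d in, %d excluded (geometry %d, outside %d, depth %d), %d valid (%.2f%% excluded over valid)\n",
    x$n_input,
    x$n_excluded_geometry + x$n_excluded_outside + x$n_excluded_depth,
    x$n_excluded_geometry, x$n_excluded_outside, x$n_excluded_depth,
    x$n_valid, x$excluded_over_valid_pct))
  invisible(x)
}
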