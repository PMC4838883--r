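# Habitat classification (littoral vs offshore), monthly use percentages,
# density grids, and Jacobs selectivity D with t-based confidence-interval
# neutrality tests. The littoral zone is lake area whose total depth is at
# or below the littoral limit (default 8 m); availability p is the wet-area
# fraction of each zone.

#' Classify fixes into habitat zones
#'
#' Littoral iff the total (bathymetric) depth at the fix is at or below the
#' littoral limit; the boundary depth itself is littoral.
#'
#' @param fixes position-fix table (QC-passed: inside the lake).
#' @param bathy a [bathy_grid()].
#' @param littoral_limit littoral depth cut, m.
#' @return Character vector `"littoral"` / `"offshore"`.
#' @export
zone_of <- function(fixes, bathy, littoral_limit = 8) {
  bed <- depth_at(bathy, fixes$x, fixes$y)
  if (any(is.na(bed)))
    stop("missing bathymetry at ", sum(is.na(bed)), " fix(es); run QC first")
  ifelse(bed <= littoral_limit, "littoral", "offshore")
}

#' Zone availability as wet-area fractions
#'
#' @param bathy a [bathy_grid()].
#' @param littoral_limit littoral depth cut, m.
#' @return Named numeric `c(p_littoral, p_offshore)`, summing to 1.
#' @export
zone_availability <- function(bathy, littoral_limit = 8) {
  wet <- !is.na(bathy$depth)
  if (!any(wet)) stop("no wet cells in bathymetry")
  p_l <- sum(bathy$depth <= littoral_limit, na.rm = TRUE) / sum(wet)
  c(p_littoral = p_l, p_offshore = 1 - p_l)
}

#' Per-fish monthly habitat-use percentages
#'
#' Littoral and offshore use as a percentage of the total positions of each
#' fish in each calendar month (civil months under the configured UTC
#' offset); months with no positions produce no row.
#'
#' @param fixes position-fix table (one or many fish).
#' @param bathy a [bathy_grid()].
#' @param config a [pipeline_config()].
#' @return `data.frame`: `fish_id`, `month` ("YYYY-MM"), `n_positions`,
#'   `pct_littoral`, `pct_offshore`.
#' @export
monthly_use <- function(fixes, bathy, config = pipeline_config()) {
  if (nrow(fixes) == 0)
    return(data.frame(fish_id = character(0), month = character(0),
                      n_positions = integer(0), pct_littoral = numeric(0),
                      pct_offshore = numeric(0)))
  zone <- zone_of(fixes, bathy, config$littoral_depth_limit)
  month <- format(fixes$t + config$utc_offset_hours * 3600, "%Y-%m",
                  tz = "UTC")
  agg <- stats::aggregate(list(n_positions = rep(1L, nrow(fixes)),
                               n_litt = zone == "littoral"),
                          list(fish_id = fixes$fish_id, month = month), sum)
  agg$pct_littoral <- 100 * agg$n_litt / agg$n_positions
  agg$pct_offshore <- 100 - agg$pct_littoral
  agg <- agg[order(agg$fish_id, agg$month),
             c("fish_id", "month", "n_positions", "pct_littoral",
               "pct_offshore")]
  rownames(agg) <- NULL
  agg
}

#' Position density grid (counts and percentages per cell)
#'
#' Counts fixes on a square lattice of the configured cell area (25 m^2 ->
#' 5 m cells), grouped by month and fish or morph, with per-cell percentage
#' of the group's positions. Percentages within a group sum to 100.
#'
#' @param fixes position-fix table.
#' @param bathy a [bathy_grid()] (supplies the lattice origin).
#' @param cell_area cell area, m^2.
#' @param group optional grouping vector (e.g. morph), recycled over fixes;
#'   default one group.
#' @param utc_offset_hours civil-time offset for month assignment.
#' @return Long-format `data.frame`: `group`, `month`, `i`, `j`, `x`, `y`
#'   (cell centres), `count`, `pct`.
#' @export
density_grid <- function(fixes, bathy, cell_area = 25, group = NULL,
                         utc_offset_hours = 1) {
  stopifnot(cell_area > 0)
  if (nrow(fixes) == 0)
    return(data.frame(group = character(0), month = character(0),
                      i = integer(0), j = integer(0), x = numeric(0),
                      y = numeric(0), count = integer(0), pct = numeric(0)))
  s <- sqrt(cell_area)
  j <- floor((fixes$x - bathy$x0) / s) + 1L
  i <- floor((fixes$y - bathy$y0) / s) + 1L
  month <- format(fixes$t + utc_offset_hours * 3600, "%Y-%m", tz = "UTC")
  grp <- if (is.null(group)) rep("all", nrow(fixes)) else
    rep_len(as.character(group), nrow(fixes))
  agg <- stats::aggregate(list(count = rep(1L, nrow(fixes))),
                          list(group = grp, month = month, i = i, j = j), sum)
  tot <- stats::ave(agg$count, agg$group, agg$month, FUN = sum)
  agg$pct <- 100 * agg$count / tot
  agg$x <- bathy$x0 + (agg$j - 0.5) * s
  agg$y <- bathy$y0 + (agg$i - 0.5) * s
  agg[order(agg$group, agg$month, agg$i, agg$j),
      c("group", "month", "i", "j", "x", "y", "count", "pct")]
}

#' Jacobs selectivity index
#'
#' `D = (r - p) / (r + p - 2 r p)`, comparing the proportion of positions
#' in a habitat (`r`) against the proportion of lake area available (`p`).
#' D ranges from -1 (complete avoidance) through 0 (use proportional to
#' availability) to +1 (exclusive use).
#'
#' @param r proportion of habitat used, in [0, 1] (vectorised).
#' @param p proportion of habitat available, in (0, 1).
#' @return D in [-1, 1].
#' @export
jacobs_D <- function(r, p) {
  if (any(p <= 0 | p >= 1)) stop("availability p must be strictly in (0, 1)")
  if (any(r < 0 | r > 1)) stop("use proportion r must be in [0, 1]")
  (r - p) / (r + p - 2 * r * p)
}

#' Morph-level monthly Jacobs selectivity with neutrality verdicts
#'
#' Computes per fish-month D for the chosen habitat from the monthly-use
#' table, then per morph-month the mean of the individual D values with a
#' 95 % t confidence interval (fish as the replicate). The verdict is
#' `preferred` when the CI lies above 0, `avoided` when below, else
#' `neutral`; with a single fish the CI is flagged unavailable.
#'
#' @param use a [monthly_use()] table.
#' @param morph_map named character vector fish_id -> morph.
#' @param p availability of the habitat, proportion in (0, 1).
#' @param habitat `"littoral"` or `"offshore"`.
#' @param conf confidence level.
#' @return `data.frame`: `morph`, `month`, `n_fish`, `mean_D`, `ci_low`,
#'   `ci_high`, `verdict`.
#' @export
morph_monthly_selectivity <- function(use, morph_map, p,
                                      habitat = c("offshore", "littoral"),
                                      conf = 0.95) {
  habitat <- match.arg(habitat)
  r <- if (habitat == "littoral") use$pct_littoral / 100 else
    use$pct_offshore / 100
  D <- jacobs_D(r, p)
  morph <- morph_map[use$fish_id]
  if (any(is.na(morph))) stop("fish without morph label in morph_map")
  sp <- split(D, list(morph = morph, month = use$month), drop = TRUE)
  rows <- lapply(names(sp), function(k) {
    d <- sp[[k]]
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    n <- length(d)
    m <- mean(d)
    if (n >= 2) {
      se <- stats::sd(d) / sqrt(n)
      tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
      lo <- m - tq * se; hi <- m + tq * se
      verdict <- if (lo > 0) "preferred" else if (hi < 0) "avoided" else "neutral"
    } else {
      lo <- NA_real_; hi <- NA_real_; verdict <- "ci_unavailable"
    }
    data.frame(morph = parts[1], month = parts[2], n_fish = n, mean_D = m,
               ci_low = lo, ci_high = hi, verdict = verdict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$morph, out$month), ]
  rownames(out) <- NULL
  out
}

#' Morph-level mean monthly habitat use (mean of individual monthly means)
#'
#' @param use a [monthly_use()] table.
#' @param morph_map named character vector fish_id -> morph.
#' @return `data.frame`: `morph`, `month`, `n_fish`, `mean_pct_littoral`,
#'   `mean_pct_offshore`, plus an annual mean-of-monthly-means per morph in
#'   the attribute `"annual"`.
#' @export
morph_monthly_use <- function(use, morph_map) {
  morph <- morph_map[use$fish_id]
  agg <- stats::aggregate(list(mean_pct_littoral = use$pct_littoral,
                               mean_pct_offshore = use$pct_offshore),
                          list(morph = morph, month = use$month), mean)
  n <- stats::aggregate(list(n_fish = rep(1L, nrow(use))),
                        list(morph = morph, month = use$month), sum)
  out <- merge(agg, n)
  out <- out[order(out$morph, out$month),
             c("morph", "month", "n_fish", "mean_pct_littoral",
               "mean_pct_offshore")]
  rownames(out) <- NULL
  annual <- stats::aggregate(
    list(pct_littoral = out$mean_pct_littoral,
         pct_offshore = out$mean_pct_offshore),
    list(morph = out$morph), mean)
  attr(out, "annual") <- annual
  out
}
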