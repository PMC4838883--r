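# Movement metrics: displacement between consecutive fixes standardised to
# body lengths per second (BLs^-1), fish depth, and distance from the lake
# bed, summarised as individual daily means and morph-level means of
# monthly means. Displacement is horizontal (2-D); depth is reported
# separately. Because fixes arrive roughly every 80 minutes, displacement
# systematically underestimates the true swimming speed.

#' Displacement rate between two fixes
#'
#' Horizontal Euclidean distance divided by elapsed time and by fork
#' length: body lengths per second.
#'
#' @param a,b single-row position fixes of the same fish, `b` later.
#' @param fork_length fork length, mm.
#' @return Displacement, BLs^-1.
#' @export
step_displacement <- function(a, b, fork_length) {
  dt <- as.numeric(difftime(b$t, a$t, units = "secs"))
  if (dt <= 0) stop("non-positive time difference between fixes")
  sqrt((b$x - a$x)^2 + (b$y - a$y)^2) / dt / (fork_length / 1000)
}

#' Distance from the lake bed
#'
#' Bathymetric depth at the fix minus tag depth. Small negative values
#' (tag slightly below the bed, within `tol`) are clamped to 0; larger
#' discordance is an error (it should have been removed by QC).
#'
#' @param fixes position-fix table.
#' @param bathy a [bathy_grid()].
#' @param tol clamp tolerance, m.
#' @return Numeric vector, metres above the bed.
#' @export
dist_from_bed <- function(fixes, bathy, tol = 1) {
  bed <- depth_at(bathy, fixes$x, fixes$y)
  if (any(is.na(bed))) stop("missing bathymetry at some fixes")
  d <- bed - fixes$tag_depth
  if (any(d < -tol))
    stop("tag depth exceeds bathymetric depth beyond tolerance at ",
         sum(d < -tol), " fix(es)")
  pmax(d, 0)
}

#' Individual daily movement summaries
#'
#' Per fish and civil date: mean displacement over steps whose later fix
#' falls on that date (steps spanning more than `gap_max_intervals`
#' nominal transmission intervals are skipped), mean tag depth, and mean
#' distance from the lake bed.
#'
#' @param fixes QC-passed position-fix table.
#' @param fish a [fish_records()] table (fork lengths).
#' @param bathy a [bathy_grid()].
#' @param config a [pipeline_config()].
#' @param nominal_interval_min nominal transmission interval, minutes.
#' @return `data.frame`: `fish_id`, `date`, `mean_displacement`,
#'   `mean_depth`, `mean_dist_from_bed`, `n_steps`, `n_fixes`.
#' @export
daily_summaries <- function(fixes, fish, bathy, config = pipeline_config(),
                            nominal_interval_min = 80) {
  fl <- stats::setNames(fish$fork_length, fish$fish_id)
  if (any(!fixes$fish_id %in% names(fl)))
    stop("fixes for fish missing from the fish table")
  gap_max <- config$gap_max_intervals * nominal_interval_min * 60
  date <- as.Date(fixes$t + config$utc_offset_hours * 3600, tz = "UTC")
  above <- dist_from_bed(fixes, bathy, config$depth_concordance_tol)

  rows <- lapply(split(seq_len(nrow(fixes)), fixes$fish_id), function(ii) {
    o <- ii[order(fixes$t[ii])]
    n <- length(o)
    dt <- as.numeric(difftime(fixes$t[o[-1]], fixes$t[o[-n]], units = "secs"))
    dd <- sqrt((fixes$x[o[-1]] - fixes$x[o[-n]])^2 +
                 (fixes$y[o[-1]] - fixes$y[o[-n]])^2)
    disp <- dd / dt / (fl[fixes$fish_id[o[1]]] / 1000)
    ok_step <- dt > 0 & dt <= gap_max
    step_date <- date[o[-1]]
    depth_by_day <- tapply(fixes$tag_depth[o], date[o], mean)
    above_by_day <- tapply(above[o], date[o], mean)
    n_by_day <- tapply(rep(1L, n), date[o], sum)
    days <- names(depth_by_day)
    disp_by_day <- tapply(disp[ok_step], as.character(step_date[ok_step]), mean)
    nstep_by_day <- tapply(rep(1L, sum(ok_step)),
                           as.character(step_date[ok_step]), sum)
    data.frame(fish_id = fixes$fish_id[o[1]], date = as.Date(days),
               mean_displacement = as.numeric(disp_by_day[days]),
               mean_depth = as.numeric(depth_by_day),
               mean_dist_from_bed = as.numeric(above_by_day),
               n_steps = as.integer(ifelse(is.na(nstep_by_day[days]), 0L,
                                           nstep_by_day[days])),
               n_fixes = as.integer(n_by_day),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fish_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Morph-level monthly and annual means of movement metrics
#'
#' Month mean = mean over fish of fish-month means of daily values; the
#' annual value is the unweighted mean of the monthly means, so months
#' enter equally regardless of the number of days or fish.
#'
#' @param daily a [daily_summaries()] table.
#' @param morph_map named character vector fish_id -> morph.
#' @return list: `monthly` (morph, month, n_fish and the three metric
#'   means), `annual` (morph-level mean of monthly means).
#' @export
morph_monthly_means <- function(daily, morph_map) {
  morph <- morph_map[daily$fish_id]
  if (any(is.na(morph))) stop("fish without morph label")
  month <- format(daily$date, "%Y-%m")
  fm <- stats::aggregate(
    daily[, c("mean_displacement", "mean_depth", "mean_dist_from_bed")],
    list(morph = morph, fish_id = daily$fish_id, month = month),
    mean, na.rm = TRUE)
  monthly <- stats::aggregate(
    fm[, c("mean_displacement", "mean_depth", "mean_dist_from_bed")],
    list(morph = fm$morph, month = fm$month), mean, na.rm = TRUE)
  nf <- stats::aggregate(list(n_fish = rep(1L, nrow(fm))),
                         list(morph = fm$morph, month = fm$month), sum)
  monthly <- merge(monthly, nf)
  monthly <- monthly[order(monthly$morph, monthly$month), ]
  rownames(monthly) <- NULL
  annual <- stats::aggregate(
    monthly[, c("mean_displacement", "mean_depth", "mean_dist_from_bed")],
    list(morph = monthly$morph), mean, na.rm = TRUE)
  list(monthly = monthly, annual = annual)
}

#' Permutation test for a morph effect on fish-level annual means
#'
#' Substitute for a mixed-model morph test: the statistic is the absolute
#' difference of morph means of fish-level annual means; the null
#' distribution is generated by permuting the fish morph labels; the
#' p-value is `(1 + #{perm >= obs}) / (1 + n_perm)`.
#'
#' @param values numeric vector of fish-level annual means.
#' @param labels morph label per fish (exactly two levels).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list: `statistic`, `p_value`, `n_perm`.
#' @export
permutation_morph_test <- function(values, labels, n_perm = 999, seed = 1L) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("exactly two morph labels required")
  if (any(table(labels) < 2)) stop("need >= 2 fish per morph")
  if (n_perm < 99) warning("fewer than 99 permutations gives a coarse p-value")
  obs <- abs(mean(values[labels == lev[1]]) - mean(values[labels == lev[2]]))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.derive_seed(seed, "perm-morph"))
  n1 <- sum(labels == lev[1])
  stat <- replicate(n_perm, {
    idx <- sample.int(length(values), n1)
    abs(mean(values[idx]) - mean(values[-idx]))
  })
  list(statistic = obs, p_value = (1 + sum(stat >= obs)) / (1 + n_perm),
       n_perm = n_perm)
}
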