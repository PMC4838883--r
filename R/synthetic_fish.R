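# Phenotype-specific trajectory simulator plus the acoustic observation
# process.
#
# Horizontal movement alternates travel and dwell: at each relocation the
# fish picks a habitat zone (littoral with probability littoral_affinity),
# swims to a destination cell of that zone at cruise speed, then forages
# around it for an exponentially distributed dwell. Destinations are
# distance-discounted so typical travel takes about an hour; legs whose
# start and end lie in the same zone are projected onto that zone, so a
# fish with affinity 1 stays littoral at every instant. The vertical
# position mean-reverts to a phenotype depth target capped just above the
# lake bed. The positioning solver itself is not simulated: observation
# error is injected directly, growing toward the shoreline.

#' Specify a behavioural phenotype for simulation
#'
#' @param name phenotype label (e.g. `"Littoral"`, `"Pelagic"`).
#' @param littoral_affinity probability that a relocation targets the
#'   littoral zone (a destination-choice probability, not an area
#'   proportion; long-run littoral occupancy tracks it, not the littoral
#'   area fraction).
#' @param step_speed_mean net movement speed scale, body lengths per
#'   second (BLs^-1); the swimming (cruise) speed is `cruise_factor`
#'   times larger, the surplus being spent on path tortuosity and dwell.
#' @param depth_target mean-reversion depth target, m.
#' @param depth_sd stationary s.d. of the vertical process, m.
#' @param fork_length fork length, mm.
#' @param monthly_activity_multiplier 12 speed multipliers (Jan..Dec).
#' @param cruise_factor cruise-to-net speed ratio (path tortuosity).
#' @param dwell_mean_min mean dwell (foraging bout) at a destination,
#'   minutes.
#' @param dwell_sd s.d. of the localized dwell movement, m.
#' @param locality_time_s distance-discount scale for destination choice,
#'   expressed as travel seconds at cruise speed.
#' @param home_radius optional radius (m) confining destinations to a disc
#'   about `home_center`; overrides zone-biased choice. Used to program
#'   home-range size contrasts with known ground truth.
#' @param home_center optional c(x, y) centre of the home disc.
#' @return A list of class `phenotype_spec`.
#' @export
phenotype_spec <- function(name, littoral_affinity = 0.5,
                           step_speed_mean = 0.06, depth_target = 10,
                           depth_sd = 3, fork_length = 300,
                           monthly_activity_multiplier = rep(1, 12),
                           cruise_factor = 3, dwell_mean_min = 300,
                           dwell_sd = 8, locality_time_s = 3600,
                           home_radius = NULL, home_center = c(0, 0)) {
  stopifnot(littoral_affinity >= 0, littoral_affinity <= 1,
            step_speed_mean >= 0, fork_length > 0, cruise_factor >= 1,
            length(monthly_activity_multiplier) == 12)
  structure(list(name = name, littoral_affinity = littoral_affinity,
                 step_speed_mean = step_speed_mean,
                 depth_target = depth_target, depth_sd = depth_sd,
                 fork_length = fork_length,
                 monthly_activity_multiplier = monthly_activity_multiplier,
                 cruise_factor = cruise_factor,
                 dwell_mean_min = dwell_mean_min, dwell_sd = dwell_sd,
                 locality_time_s = locality_time_s,
                 home_radius = home_radius, home_center = home_center),
            class = "phenotype_spec")
}

#' Specify the acoustic observation process
#'
#' @param nominal_interval nominal transmission interval, minutes.
#' @param interval_jitter half-width of the uniform jitter on the interval,
#'   minutes.
#' @param position_error_sd baseline isotropic positional error s.d., m.
#' @param error_geometry_factor growth of the error multiplier with squared
#'   relative distance from the lake centre (factor = 1 + egf * (r/R)^2).
#' @param depth_resolution pressure-sensor resolution, m.
#' @param max_sensor_depth sensor range, m.
#' @param detection_prob per-transmission detection probability.
#' @param dropout_dates optional list of `c(start, end)` POSIXct intervals
#'   during which no fixes are produced.
#' @return A list of class `telemetry_spec`.
#' @export
telemetry_spec <- function(nominal_interval = 80, interval_jitter = 25,
                           position_error_sd = 2, error_geometry_factor = 1.5,
                           depth_resolution = 0.22, max_sensor_depth = 50,
                           detection_prob = 0.9, dropout_dates = NULL) {
  stopifnot(nominal_interval > 0, detection_prob > 0, detection_prob <= 1,
            interval_jitter >= 0, interval_jitter < nominal_interval)
  structure(list(nominal_interval = nominal_interval,
                 interval_jitter = interval_jitter,
                 position_error_sd = position_error_sd,
                 error_geometry_factor = error_geometry_factor,
                 depth_resolution = depth_resolution,
                 max_sensor_depth = max_sensor_depth,
                 detection_prob = detection_prob,
                 dropout_dates = dropout_dates),
            class = "telemetry_spec")
}

# wet cell centres, optionally excluding cells at or shallower than
# min_depth (ice restriction)
.zone_cells <- function(lake, littoral_limit, min_depth = 0) {
  g <- lake$bathy
  d <- g$depth
  wet <- which(!is.na(d) & d > min_depth, arr.ind = TRUE)
  if (nrow(wet) == 0) stop("no available wet cells")
  cx <- g$x0 + (wet[, 2] - 0.5) * g$cell_size
  cy <- g$y0 + (wet[, 1] - 0.5) * g$cell_size
  dep <- d[wet]
  list(x = cx, y = cy, depth = dep, littoral = dep <= littoral_limit)
}

# binary shrink toward the lake centre until wet; the synthetic basin is
# star-shaped about the origin
.pull_inside <- function(bathy, x, y) {
  bad <- is.na(depth_at(bathy, x, y))
  it <- 0
  while (any(bad) && it < 80) {
    x[bad] <- x[bad] * 0.97
    y[bad] <- y[bad] * 0.97
    bad <- is.na(depth_at(bathy, x, y))
    it <- it + 1
  }
  list(x = x, y = y)
}

# radially project points onto a habitat zone: littoral points move outward
# (inward if dry), offshore points move inward, in ~0.8 % radius steps
.project_to_zone <- function(bathy, x, y, littoral, limit) {
  for (it in 1:400) {
    bed <- depth_at(bathy, x, y)
    if (littoral) {
      out_b <- is.na(bed)            # beyond shoreline: come back in
      deep <- !is.na(bed) & bed > limit
      if (!any(out_b) && !any(deep)) break
      x[deep] <- x[deep] * 1.008; y[deep] <- y[deep] * 1.008
      x[out_b] <- x[out_b] * 0.992; y[out_b] <- y[out_b] * 0.992
    } else {
      bad <- is.na(bed) | bed <= limit
      if (!any(bad)) break
      x[bad] <- x[bad] * 0.985; y[bad] <- y[bad] * 0.985
    }
  }
  list(x = x, y = y)
}

# dense path between two points: polar interpolation (radius linear, angle
# along the shorter arc) keeps same-zone legs close to their zone annulus
.polar_path <- function(p, q, npts = 64) {
  r1 <- sqrt(sum(p^2)); r2 <- sqrt(sum(q^2))
  th1 <- atan2(p[2], p[1]); th2 <- atan2(q[2], q[1])
  dth <- ((th2 - th1 + pi) %% (2 * pi)) - pi
  s <- seq(0, 1, length.out = npts)
  r <- r1 + s * (r2 - r1)
  th <- th1 + s * dth
  cbind(r * cos(th), r * sin(th))
}

#' Simulate one fish's true trajectory
#'
#' Travel/dwell relocation walk at `dt`-second resolution (see the module
#' description above), with a mean-reverting depth process capped 0.1 m
#' above the lake bed.
#'
#' @param lake a lake from [make_lake()].
#' @param phenotype a [phenotype_spec()].
#' @param start POSIXct start time (UTC).
#' @param days track duration, days.
#' @param seed integer seed.
#' @param dt truth sampling resolution, seconds.
#' @param ice optional list `(start, end, thickness)`: during the interval,
#'   cells with total depth at or below `thickness` metres are unavailable
#'   as destinations (ice-restricted shallow habitat).
#' @param utc_offset_hours civil-time offset used for month assignment.
#' @return A list of class `truth_track`: `fish_id`, vectors `t`, `x`, `y`,
#'   `depth`, the fork length, and `monthly_littoral` (true per-month
#'   littoral occupancy fractions).
#' @export
simulate_track <- function(lake, phenotype, start, days, seed, dt = 60,
                           ice = NULL, utc_offset_hours = 1) {
  stopifnot(inherits(phenotype, "phenotype_spec"), inherits(start, "POSIXct"))
  limit <- lake$spec$littoral_limit
  cells <- .zone_cells(lake, limit)
  if (!any(cells$littoral) || !any(!cells$littoral))
    stop("lake must contain both littoral and offshore cells")
  ice_cells <- if (!is.null(ice))
    .zone_cells(lake, limit, min_depth = ice$thickness) else NULL

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.derive_seed(seed, paste0("track-", phenotype$name)))

  n <- as.integer(ceiling(days * 86400 / dt)) + 1L  # endpoint inclusive
  tt <- start + (seq_len(n) - 1L) * dt
  FL_m <- phenotype$fork_length / 1000
  cs <- lake$bathy$cell_size
  mon <- as.integer(format(tt, "%m", tz = "UTC"))
  homing <- !is.null(phenotype$home_radius)

  x <- numeric(n); y <- numeric(n)

  draw_dest <- function(p0, t_now, v_cruise) {
    if (homing) {
      for (try in 1:200) {
        a <- stats::runif(1, 0, 2 * pi)
        r <- phenotype$home_radius * sqrt(stats::runif(1))
        px <- phenotype$home_center[1] + r * cos(a)
        py <- phenotype$home_center[2] + r * sin(a)
        if (!is.na(depth_at(lake$bathy, px, py)))
          return(list(xy = c(px, py), littoral = NA))
      }
      stop("home disc contains no wet cells")
    }
    cc <- cells
    if (!is.null(ice) && t_now >= ice$start && t_now <= ice$end) cc <- ice_cells
    litt <- stats::runif(1) < phenotype$littoral_affinity
    pool <- if (litt) which(cc$littoral) else which(!cc$littoral)
    if (length(pool) == 0) pool <- seq_along(cc$x)
    lambda <- max(v_cruise * phenotype$locality_time_s, 4 * cs)
    d0 <- sqrt((cc$x[pool] - p0[1])^2 + (cc$y[pool] - p0[2])^2)
    w <- exp(-d0 / lambda)
    k <- pool[sample.int(length(pool), 1, prob = w)]
    list(xy = c(cc$x[k] + stats::runif(1, -cs / 3, cs / 3),
                cc$y[k] + stats::runif(1, -cs / 3, cs / 3)),
         littoral = litt)
  }

  zone_at <- function(p) {
    bed <- depth_at(lake$bathy, p[1], p[2])
    !is.na(bed) && bed <= limit
  }

  # initial position: a destination of the preferred kind
  init <- draw_dest(c(0, 0), tt[1], 1)
  pos <- init$xy

  if (phenotype$step_speed_mean <= 0) {
    x[] <- pos[1]; y[] <- pos[2]
  } else {
    i <- 1L
    while (i <= n) {
      v_net <- phenotype$step_speed_mean *
        phenotype$monthly_activity_multiplier[mon[i]] * FL_m
      v_cruise <- v_net * phenotype$cruise_factor *
        stats::rlnorm(1, -0.045, 0.3)
      dest <- draw_dest(pos, tt[i], v_cruise)
      same_zone <- !homing && !is.na(dest$littoral) &&
        zone_at(pos) == dest$littoral
      path <- if (homing) {
        s <- seq(0, 1, length.out = 64)
        cbind(pos[1] + s * (dest$xy[1] - pos[1]),
              pos[2] + s * (dest$xy[2] - pos[2]))
      } else .polar_path(pos, dest$xy)
      seg <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
      L <- sum(seg)
      k_t <- as.integer(ceiling((L / v_cruise) / dt))
      k_t <- max(0L, min(k_t, n - i + 1L))
      if (k_t > 0) {
        s_arc <- pmin(v_cruise * seq_len(k_t) * dt, L)
        cum <- c(0, cumsum(seg))
        px <- stats::approx(cum, path[, 1], xout = s_arc)$y
        py <- stats::approx(cum, path[, 2], xout = s_arc)$y
        if (same_zone) {
          pr <- .project_to_zone(lake$bathy, px, py, dest$littoral, limit)
        } else {
          pr <- .pull_inside(lake$bathy, px, py)
        }
        idx <- i:(i + k_t - 1L)
        x[idx] <- pr$x; y[idx] <- pr$y
        pos <- c(pr$x[k_t], pr$y[k_t])
        i <- i + k_t
      }
      if (i > n) break
      # dwell: localized correlated jitter about the destination
      k_d <- as.integer(ceiling(stats::rexp(1, 1 / phenotype$dwell_mean_min) *
                                  60 / dt))
      k_d <- max(1L, min(k_d, n - i + 1L))
      rho <- 0.9
      ex <- stats::rnorm(k_d, 0, phenotype$dwell_sd * sqrt(1 - rho^2))
      ey <- stats::rnorm(k_d, 0, phenotype$dwell_sd * sqrt(1 - rho^2))
      dx <- as.numeric(stats::filter(ex, rho, method = "recursive"))
      dy <- as.numeric(stats::filter(ey, rho, method = "recursive"))
      px <- pos[1] + dx; py <- pos[2] + dy
      if (!homing && !is.na(dest$littoral)) {
        pr <- .project_to_zone(lake$bathy, px, py, dest$littoral, limit)
      } else {
        pr <- .pull_inside(lake$bathy, px, py)
      }
      idx <- i:(i + k_d - 1L)
      x[idx] <- pr$x; y[idx] <- pr$y
      pos <- c(pr$x[k_d], pr$y[k_d])
      i <- i + k_d
    }
  }

  bed <- depth_at(lake$bathy, x, y)
  alpha <- 0.95 ^ (dt / 60)
  eps <- stats::rnorm(n, 0, phenotype$depth_sd * sqrt(1 - alpha^2))
  depth <- phenotype$depth_target +
    as.numeric(stats::filter(eps, alpha, method = "recursive"))
  depth <- pmin(pmax(depth, 0), pmax(bed - 0.1, 0))

  litt <- bed <= limit
  mkey <- format(tt + utc_offset_hours * 3600, "%Y-%m", tz = "UTC")
  monthly <- stats::aggregate(litt, list(month = mkey), mean)
  names(monthly)[2] <- "true_littoral_frac"

  structure(list(fish_id = phenotype$name, t = tt, x = x, y = y,
                 depth = depth, fork_length = phenotype$fork_length,
                 monthly_littoral = monthly),
            class = "truth_track")
}

#' Observe a true track through the acoustic positioning process
#'
#' Quasi-periodic transmissions (uniform jitter about the nominal interval),
#' Bernoulli detection, isotropic Gaussian position error scaled by a
#' geometry factor growing toward the shore, and tag depth quantised to the
#' sensor resolution. The `err` field records the realised geometry factor.
#'
#' @param truth a [simulate_track()] result.
#' @param tele a [telemetry_spec()].
#' @param seed integer seed.
#' @param shore_radius reference radius for the geometry factor, m
#'   (defaults to the track's maximum distance from the origin).
#' @return A position-fix table (see [position_fixes()]).
#' @export
observe_track <- function(truth, tele, seed, shore_radius = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.derive_seed(seed, paste0("obs-", truth$fish_id)))

  n <- length(truth$t)
  t0 <- truth$t[1]
  span_min <- as.numeric(difftime(truth$t[n], t0, units = "mins"))
  n_tx <- ceiling(span_min / max(tele$nominal_interval - tele$interval_jitter, 1)) + 2
  gaps <- stats::runif(n_tx, tele$nominal_interval - tele$interval_jitter,
                       tele$nominal_interval + tele$interval_jitter)
  tx_min <- cumsum(gaps)
  tx_min <- tx_min[tx_min <= span_min]
  detected <- stats::runif(length(tx_min)) <= tele$detection_prob
  tx_min <- tx_min[detected]
  if (!is.null(tele$dropout_dates)) {
    tx_t <- t0 + tx_min * 60
    drop <- rep(FALSE, length(tx_t))
    for (iv in tele$dropout_dates)
      drop <- drop | (tx_t >= iv[1] & tx_t <= iv[2])
    tx_min <- tx_min[!drop]
  }
  if (length(tx_min) == 0)
    return(position_fixes(character(0), as.POSIXct(character(0), tz = "UTC"),
                          numeric(0), numeric(0), numeric(0), numeric(0)))

  dt <- as.numeric(difftime(truth$t[2], truth$t[1], units = "secs"))
  idx <- pmin(n, pmax(1L, as.integer(round(tx_min * 60 / dt)) + 1L))
  r <- sqrt(truth$x[idx]^2 + truth$y[idx]^2)
  R <- if (is.null(shore_radius)) max(sqrt(truth$x^2 + truth$y^2), 1) else shore_radius
  gfac <- 1 + tele$error_geometry_factor * (r / R)^2
  sd_xy <- tele$position_error_sd * gfac
  ox <- truth$x[idx] + stats::rnorm(length(idx), 0, sd_xy)
  oy <- truth$y[idx] + stats::rnorm(length(idx), 0, sd_xy)
  od <- round(pmin(truth$depth[idx], tele$max_sensor_depth) /
                tele$depth_resolution) * tele$depth_resolution
  position_fixes(truth$fish_id, t0 + round(tx_min * 60), ox, oy, od, gfac)
}

#' Simulate a tagged cohort of two (or more) phenotypes
#'
#' Orchestrates [simulate_track()] and [observe_track()] for
#' `n_per_morph[i]` fish of each phenotype, deterministic given `seed`.
#' Fish fork lengths are jittered around the phenotype value (s.d. 5 %).
#'
#' @param lake a [make_lake()] result.
#' @param phenotypes list of [phenotype_spec()]s (one per morph).
#' @param n_per_morph integer vector, fish per phenotype.
#' @param start POSIXct cohort start (UTC).
#' @param days tracking duration, days.
#' @param tele a [telemetry_spec()].
#' @param seed integer seed.
#' @param ... further arguments passed to [simulate_track()] (`dt`, `ice`,
#'   `utc_offset_hours`).
#' @return A list: `fixes` (all observed positions), `truth` (named list of
#'   truth tracks), `fish` (a [fish_records()] table with a `phenotype`
#'   column).
#' @export
simulate_cohort <- function(lake, phenotypes, n_per_morph, start, days,
                            tele = telemetry_spec(), seed = 1L, ...) {
  stopifnot(length(phenotypes) == length(n_per_morph))
  all_fixes <- list(); truth <- list()
  ids <- character(0); morphs <- character(0); fls <- numeric(0)
  shore_R <- sqrt(lake$polygon$area / pi)
  for (m in seq_along(phenotypes)) {
    ph <- phenotypes[[m]]
    for (i in seq_len(n_per_morph[m])) {
      id <- sprintf("%s%02d", substr(ph$name, 1, 1), i)
      fseed <- .derive_seed(seed, id)
      old <- .Random.seed_save()
      set.seed(.derive_seed(fseed, "fl"))
      fl <- ph$fork_length * stats::rlnorm(1, 0, 0.05)
      .Random.seed_restore(old)
      phi <- ph
      phi$fork_length <- fl
      phi$name <- id
      tr <- simulate_track(lake, phi, start, days, fseed, ...)
      fx <- observe_track(tr, tele, fseed, shore_radius = shore_R)
      truth[[id]] <- tr
      all_fixes[[id]] <- fx
      ids <- c(ids, id); morphs <- c(morphs, ph$name); fls <- c(fls, fl)
    }
  }
  fixes <- do.call(rbind, all_fixes)
  rownames(fixes) <- NULL
  mass <- 10 ^ (-5.1) * fls ^ 3.05  # length-mass allometry, g
  fish <- fish_records(ids,
                       ifelse(morphs %in% c("Littoral", "Pelagic",
                                            "DwarfMaturing", "Other"),
                              morphs, "Other"),
                       fls, mass, rep(2.9, length(ids)))
  fish$phenotype <- morphs
  list(fixes = fixes, truth = truth, fish = fish)
}
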