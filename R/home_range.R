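# Monthly home ranges: time-stratified subsampling to a fixed number of
# positions, bivariate Gaussian kernel utilization distributions, K50/K95
# isopleth areas by cumulative-mass cell ranking, and clipping of the area
# estimate to the lake boundary (mass is not renormalised: the paper-style
# workflow clips the area estimate, not the UD).

# Largest-remainder apportionment of n over strata with capacities cap;
# strata with fewer positions than their quota hand the shortfall back for
# re-apportionment over the remaining strata. Ties broken by stratum order.
largest_remainder_quota <- function(cap, n) {
  k <- length(cap)
  quota <- integer(k)
  open <- cap > 0
  n_left <- min(n, sum(cap))
  while (n_left > 0 && any(open)) {
    w <- cap[open] - quota[open]
    raw <- n_left * (cap[open] / sum(cap[open]))
    q <- floor(raw)
    rem <- raw - q
    extra <- n_left - sum(q)
    if (extra > 0) {
      ord <- order(-rem, seq_along(rem))
      q[ord[seq_len(extra)]] <- q[ord[seq_len(extra)]] + 1L
    }
    alloc <- pmin(q, cap[open] - quota[open])
    quota[open] <- quota[open] + alloc
    n_left <- n_left - sum(alloc)
    open <- cap > quota
    if (sum(alloc) == 0) break
  }
  quota
}

#' Time-stratified subsample of one fish-month's positions
#'
#' Positions are stratified by diel time category crossed with 3-hour
#' block; quotas follow largest-remainder apportionment of `n` proportional
#' to each stratum's share of available positions (re-apportioning any
#' stratum shortfall), and positions are sampled without replacement within
#' strata. Deterministic given `seed`.
#'
#' @param fixes position-fix table of one fish-month.
#' @param cal a [build_calendar()] calendar covering the fixes.
#' @param n target sample size (e.g. 54).
#' @param seed integer seed.
#' @param config a [pipeline_config()].
#' @return list: `sample` (selected fixes), `strata` (per-stratum
#'   available/quota/selected), `under_sampled` flag.
#' @export
stratified_subsample <- function(fixes, cal, n, seed,
                                 config = pipeline_config()) {
  stopifnot(n >= 1)
  if (nrow(fixes) == 0)
    return(list(sample = fixes, strata = NULL, under_sampled = TRUE))
  categ <- categorize(fixes$t, cal, config$twilight_window_min,
                      config$utc_offset_hours)
  block <- time_block(fixes$t, config$time_block_hours,
                      config$utc_offset_hours)
  key <- paste(categ, block, sep = ":")
  # stratum order: chronological by first appearance (deterministic ties)
  lev <- key[!duplicated(key)]
  key <- factor(key, levels = lev)
  cap <- as.integer(table(key))
  quota <- largest_remainder_quota(cap, n)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.derive_seed(seed, "stratified-subsample"))
  idx <- unlist(lapply(seq_along(lev), function(s) {
    pool <- which(key == lev[s])
    if (quota[s] >= length(pool)) pool else
      pool[sample.int(length(pool), quota[s])]
  }))
  idx <- sort(idx)
  strata <- data.frame(stratum = lev, available = cap, quota = quota,
                       selected = quota, stringsAsFactors = FALSE)
  list(sample = fixes[idx, , drop = FALSE], strata = strata,
       under_sampled = nrow(fixes) < n)
}

#' Bivariate Gaussian kernel utilization distribution
#'
#' Product Gaussian kernel with a single bandwidth `h` on a square
#' evaluation grid (the point bounding box padded by `4h`). The reference
#' bandwidth is `href = sigma_hat * n^(-1/6)` with
#' `sigma_hat = sqrt((var_x + var_y) / 2)`. Density is normalised to
#' integrate to 1 over the grid.
#'
#' @param x,y point coordinates, m (>= 5 points).
#' @param bandwidth `"href"` or a fixed numeric bandwidth, m.
#' @param cell evaluation cell size, m.
#' @param min_bandwidth fallback bandwidth when points are degenerate, m.
#' @return list of class `kernel_ud`: `gx`, `gy` (cell-centre coordinates),
#'   `density` (matrix, rows = y), `cell`, `h`, `n`.
#' @export
kernel_ud <- function(x, y, bandwidth = "href", cell = 5,
                      min_bandwidth = 1) {
  n <- length(x)
  if (n < 5) stop("kernel UD needs at least 5 positions")
  if (identical(bandwidth, "href")) {
    sig <- sqrt((stats::var(x) + stats::var(y)) / 2)
    h <- sig * n^(-1 / 6)
    if (!is.finite(h) || h < min_bandwidth) {
      warning("degenerate point spread; falling back to minimum bandwidth")
      h <- min_bandwidth
    }
  } else {
    h <- as.numeric(bandwidth)
    stopifnot(h > 0)
  }
  pad <- 4 * h
  gx <- seq(floor((min(x) - pad) / cell) * cell + cell / 2,
            max(x) + pad, by = cell)
  gy <- seq(floor((min(y) - pad) / cell) * cell + cell / 2,
            max(y) + pad, by = cell)
  Dx <- stats::dnorm(outer(gx, x, "-"), sd = h)   # |gx| x n
  Dy <- stats::dnorm(outer(gy, y, "-"), sd = h)   # |gy| x n
  dens <- (Dy %*% t(Dx)) / n
  mass <- sum(dens) * cell^2
  structure(list(gx = gx, gy = gy, density = dens / mass, cell = cell,
                 h = h, n = n, raw_mass = mass),
            class = "kernel_ud")
}

# cells of the prob-isopleth: indices of the smallest set of cells whose
# summed mass reaches prob (cells ranked by density, threshold included)
.isopleth_cells <- function(ud, prob) {
  stopifnot(prob > 0, prob < 1)
  d <- as.vector(ud$density)
  ord <- order(d, decreasing = TRUE)
  mass <- cumsum(d[ord]) * ud$cell^2
  k <- which(mass >= prob)[1]
  if (is.na(k)) k <- length(ord)
  ord[seq_len(k)]
}

#' Isopleth area of a utilization distribution
#'
#' Area of the smallest set of grid cells whose summed probability mass
#' reaches `prob` (cumulative-mass cell ranking; the threshold cell is
#' included).
#'
#' @param ud a [kernel_ud()].
#' @param prob isopleth probability in (0, 1), e.g. 0.95 for K95.
#' @return Area, m^2.
#' @export
isopleth_area <- function(ud, prob) {
  length(.isopleth_cells(ud, prob)) * ud$cell^2
}

#' Clip an isopleth to the lake boundary
#'
#' Removes isopleth cells whose centres fall outside the polygon and
#' returns the remaining area; the UD mass is not renormalised (the area
#' estimate is clipped, not the distribution).
#'
#' @param ud a [kernel_ud()].
#' @param prob isopleth probability.
#' @param polygon a [lake_polygon()].
#' @return list: `area_m2`, `area_ha`, `unclipped_m2`, `clipped` (flag:
#'   any cell removed).
#' @export
clip_to_lake <- function(ud, prob, polygon) {
  cells <- .isopleth_cells(ud, prob)
  ngy <- length(ud$gy)
  iy <- (cells - 1L) %% ngy + 1L
  ix <- (cells - 1L) %/% ngy + 1L
  inside <- point_in_polygon(polygon, ud$gx[ix], ud$gy[iy])
  area <- sum(inside) * ud$cell^2
  list(area_m2 = area, area_ha = area / 1e4,
       unclipped_m2 = length(cells) * ud$cell^2,
       clipped = any(!inside))
}

#' Incremental area analysis
#'
#' Recomputes the K95 kernel area on nested position prefixes
#' (k = 5..n) and reports the smallest k at which the area has reached an
#' asymptote: all areas over the next five increments stay within 5 % of
#' the area at k.
#'
#' @param x,y positions in sampling order (>= 5).
#' @param bandwidth passed to [kernel_ud()].
#' @param cell evaluation cell, m.
#' @param prob isopleth probability.
#' @return list: `curve` (data.frame k, area_m2), `asymptote_k`.
#' @export
incremental_area <- function(x, y, bandwidth = "href", cell = 5,
                             prob = 0.95) {
  n <- length(x)
  if (n < 5) stop("incremental area analysis needs at least 5 positions")
  ks <- 5:n
  areas <- vapply(ks, function(k) {
    ud <- suppressWarnings(kernel_ud(x[1:k], y[1:k], bandwidth, cell))
    isopleth_area(ud, prob)
  }, numeric(1))
  asym <- NA_integer_
  for (i in seq_along(ks)) {
    win <- i:min(i + 5, length(ks))
    if (all(abs(areas[win] - areas[i]) / areas[i] < 0.05)) {
      asym <- ks[i]
      break
    }
  }
  list(curve = data.frame(k = ks, area_m2 = areas), asymptote_k = asym)
}

#' Monthly home-range table for a tracked cohort
#'
#' Per fish-month: stratified subsample to the configured size, reference
#' kernel UD, K50/K95 isopleth areas clipped to the lake boundary, in
#' hectares. Fish-months with fewer than 5 positions are skipped and
#' logged in the `skipped` attribute.
#'
#' @param fixes QC-passed position-fix table (all fish).
#' @param cal a [build_calendar()] calendar.
#' @param polygon a [lake_polygon()].
#' @param config a [pipeline_config()].
#' @param seed integer seed for the subsampling.
#' @return `data.frame`: `fish_id`, `month`, `n_available`, `n_used`, `h`,
#'   `K50_ha`, `K95_ha`, `clipped`, `under_sampled`.
#' @export
monthly_home_ranges <- function(fixes, cal, polygon,
                                config = pipeline_config(), seed = 1L) {
  month <- format(fixes$t + config$utc_offset_hours * 3600, "%Y-%m",
                  tz = "UTC")
  keys <- unique(data.frame(fish_id = fixes$fish_id, month = month,
                            stringsAsFactors = FALSE))
  keys <- keys[order(keys$fish_id, keys$month), , drop = FALSE]
  rows <- list(); skipped <- character(0)
  iso <- sort(config$kde_isopleths)
  for (r in seq_len(nrow(keys))) {
    sel <- fixes$fish_id == keys$fish_id[r] & month == keys$month[r]
    fm <- fixes[sel, , drop = FALSE]
    if (nrow(fm) < 5) {
      skipped <- c(skipped, paste0(keys$fish_id[r], ":", keys$month[r]))
      next
    }
    ss <- stratified_subsample(fm, cal, config$homerange_sample_n,
                               .derive_seed(seed, paste0(keys$fish_id[r],
                                                         keys$month[r])),
                               config)
    pts <- ss$sample
    ud <- suppressWarnings(kernel_ud(pts$x, pts$y))
    a50 <- clip_to_lake(ud, iso[1], polygon)
    a95 <- clip_to_lake(ud, iso[2], polygon)
    rows[[length(rows) + 1L]] <- data.frame(
      fish_id = keys$fish_id[r], month = keys$month[r],
      n_available = nrow(fm), n_used = nrow(pts), h = ud$h,
      K50_ha = a50$area_ha, K95_ha = a95$area_ha,
      clipped = a50$clipped || a95$clipped,
      under_sampled = ss$under_sampled, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fish_id = character(0), month = character(0),
               n_available = integer(0), n_used = integer(0), h = numeric(0),
               K50_ha = numeric(0), K95_ha = numeric(0), clipped = logical(0),
               under_sampled = logical(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
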