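# Parametric single-basin lake generator.
#
# The basin is a radial depth profile inside a gently perturbed shoreline:
#   depth(x, y) = D * f(u) * (1 + amp * s(theta, u) * 4u(1-u)),  u = r / R(theta)
# where f is the shape profile, D the maximum depth, and s a smooth
# low-amplitude harmonic field. The taper 4u(1-u) vanishes at the centre and
# the shore, so the maximum depth and the shoreline are exact. The shape
# exponent is solved in closed form so the area shallower than the littoral
# depth limit matches a target fraction of the wet area.

#' Specify a synthetic single-basin lake
#'
#' @param surface_area_km2 target lake surface area, km^2.
#' @param max_depth maximum depth, m.
#' @param littoral_fraction_target fraction of wet area with total depth at
#'   or below `littoral_limit` (0 < target < 1).
#' @param basin_shape `"cone"` (depth profile `D * (1 - u)^m`) or `"bowl"`
#'   (super-ellipse profile `D * (1 - u^k)`), `u` the relative radius.
#' @param shape_exponent optional fixed profile exponent; when `NULL` the
#'   exponent is solved so the littoral-fraction target is met.
#' @param cell_size bathymetry cell edge, m.
#' @param littoral_limit littoral depth cut used when solving the shape, m.
#' @param noise_amp relative amplitude of the smooth depth/shoreline
#'   perturbation (<= 0.05).
#' @param rng_seed integer seed for the perturbation harmonics.
#' @return A list of class `lake_spec`.
#' @export
lake_spec <- function(surface_area_km2 = 0.71, max_depth = 34,
                      littoral_fraction_target = 0.225,
                      basin_shape = c("cone", "bowl"),
                      shape_exponent = NULL,
                      cell_size = 5, littoral_limit = 8,
                      noise_amp = 0.03, rng_seed = 1L) {
  basin_shape <- match.arg(basin_shape)
  stopifnot(littoral_fraction_target > 0, littoral_fraction_target < 1,
            surface_area_km2 > 0, max_depth > 0, cell_size > 0,
            noise_amp >= 0, noise_amp <= 0.05)
  structure(list(surface_area_km2 = surface_area_km2, max_depth = max_depth,
                 littoral_fraction_target = littoral_fraction_target,
                 basin_shape = basin_shape, shape_exponent = shape_exponent,
                 cell_size = cell_size, littoral_limit = littoral_limit,
                 noise_amp = noise_amp, rng_seed = as.integer(rng_seed)),
            class = "lake_spec")
}

# Closed-form exponent giving littoral fraction f for relative littoral
# depth z = limit / max_depth.
#   bowl: fraction = 1 - (1 - z)^(2/k)  =>  k = 2 log(1-z) / log(1-f)
#   cone: fraction = 1 - (1 - z^(1/m))^2 => m = log(z) / log(1 - sqrt(1-f))
solve_shape_exponent <- function(shape, z, f) {
  if (z >= 1) return(1)  # whole basin littoral regardless of exponent
  e <- switch(shape,
    bowl = 2 * log(1 - z) / log(1 - f),
    cone = log(z) / log(1 - sqrt(1 - f)))
  if (!is.finite(e) || e <= 0)
    stop(sprintf(
      "littoral fraction %.3f unattainable for shape '%s'; try a target in (0, 1) and max depth above the littoral limit",
      f, shape))
  e
}

# Analytic littoral area fraction of the noise-free radial profile.
littoral_fraction_analytic <- function(shape, z, exponent) {
  if (z >= 1) return(1)
  switch(shape,
    bowl = 1 - (1 - z)^(2 / exponent),
    cone = 1 - (1 - z^(1 / exponent))^2)
}

# Smooth periodic harmonic field on (theta); coefficients seeded.
harmonic_field <- function(seed, n_harmonics = 4) {
  rs <- .derive_seed(seed, "lake-noise")
  old <- .Random.seed_save()
  set.seed(rs)
  amp <- stats::rnorm(n_harmonics) / sqrt(n_harmonics)
  pha <- stats::runif(n_harmonics, 0, 2 * pi)
  .Random.seed_restore(old)
  function(theta) {
    s <- 0
    for (h in seq_along(amp)) s <- s + amp[h] * sin((h + 1) * theta + pha[h])
    s / max(1, max(abs(amp)) * 2)  # keep |s| <= ~1
  }
}

#' Generate a synthetic lake: bathymetry grid plus boundary polygon
#'
#' Builds the radial basin described in [lake_spec()], classifies cells as
#' wet where the cell centre lies inside the (perturbed) shoreline, and
#' traces the exact outline of the wet-cell union as the boundary polygon,
#' so the polygon area equals the wet grid area by construction.
#'
#' @param spec a [lake_spec()].
#' @return A list with elements `bathy` ([bathy_grid()]), `polygon`
#'   ([lake_polygon()]), `littoral_fraction` (realised), `p_littoral`,
#'   `p_offshore`, `shape_exponent` and `spec`.
#' @export
make_lake <- function(spec) {
  stopifnot(inherits(spec, "lake_spec"))
  D <- spec$max_depth
  z <- spec$littoral_limit / D
  expo <- spec$shape_exponent
  if (is.null(expo))
    expo <- solve_shape_exponent(spec$basin_shape, z,
                                 spec$littoral_fraction_target)
  area_m2 <- spec$surface_area_km2 * 1e6
  R0 <- sqrt(area_m2 / pi)
  s_field <- harmonic_field(spec$rng_seed)

  # shoreline radius R(theta); normalised so the enclosed area stays on target
  shore <- function(theta) R0 * (1 + spec$noise_amp * s_field(theta))
  th_ref <- seq(0, 2 * pi, length.out = 2048)
  scale_area <- sqrt(mean(shore(th_ref)^2) / R0^2)
  shoreR <- function(theta) shore(theta) / scale_area

  half <- max(shoreR(th_ref)) + 2 * spec$cell_size
  n_cells <- ceiling(2 * half / spec$cell_size)
  x0 <- -n_cells * spec$cell_size / 2
  y0 <- x0
  cx <- x0 + (seq_len(n_cells) - 0.5) * spec$cell_size
  cy <- y0 + (seq_len(n_cells) - 0.5) * spec$cell_size
  xx <- matrix(cx, n_cells, n_cells, byrow = TRUE)
  yy <- matrix(cy, n_cells, n_cells)
  r <- sqrt(xx^2 + yy^2)
  theta <- atan2(yy, xx)
  u <- r / shoreR(theta)

  f <- switch(spec$basin_shape,
    cone = (1 - pmin(u, 1))^expo,
    bowl = pmax(0, 1 - pmin(u, 1)^expo))
  taper <- 4 * u * (1 - u)
  depth <- D * f * (1 + spec$noise_amp * s_field(3 * theta + 1) * taper)
  depth[u >= 1] <- NA
  depth[depth < 0 & !is.na(depth)] <- 0

  bathy <- bathy_grid(x0, y0, spec$cell_size, depth)
  mask <- !is.na(depth)
  poly <- trace_cell_outline(mask, x0, y0, spec$cell_size)

  wet <- sum(mask)
  litt <- sum(depth <= spec$littoral_limit, na.rm = TRUE)
  realised <- litt / wet
  list(bathy = bathy, polygon = poly,
       littoral_fraction = realised,
       p_littoral = realised, p_offshore = 1 - realised,
       shape_exponent = expo, spec = spec)
}

#' Trace the outline of a wet-cell union as a polygon
#'
#' Walks the axis-aligned boundary edges of a simply-connected cell mask
#' (TRUE = wet), keeping wet cells on the left, and returns the closed
#' outline. The polygon area equals `sum(mask) * s^2` exactly.
#'
#' @param mask logical matrix (rows = y from y-min, cols = x from x-min).
#' @param x0,y0 grid origin (lower-left corner), m.
#' @param s cell size, m.
#' @return A [lake_polygon()].
#' @export
trace_cell_outline <- function(mask, x0, y0, s) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  # directed boundary edges (wet on the left), vertices on the grid lattice.
  # vertex (a, b) = lattice corner at x = x0 + (a-1)s, y = y0 + (b-1)s.
  from <- integer(0); to <- integer(0)
  key <- function(a, b) a * (nr + 2L) + b
  wet <- which(pad, arr.ind = TRUE)
  i <- wet[, 1]; j <- wet[, 2]
  # south edge exposed: neighbour below dry -> edge west->east along bottom
  e <- !pad[cbind(i - 1L, j)]
  from <- c(from, key(j[e] - 1L, i[e] - 1L)); to <- c(to, key(j[e], i[e] - 1L))
  # east edge: neighbour right dry -> edge south->north along right side
  e <- !pad[cbind(i, j + 1L)]
  from <- c(from, key(j[e], i[e] - 1L)); to <- c(to, key(j[e], i[e]))
  # north edge: neighbour above dry -> east->west along top
  e <- !pad[cbind(i + 1L, j)]
  from <- c(from, key(j[e], i[e])); to <- c(to, key(j[e] - 1L, i[e]))
  # west edge: neighbour left dry -> north->south along left side
  e <- !pad[cbind(i, j - 1L)]
  from <- c(from, key(j[e] - 1L, i[e])); to <- c(to, key(j[e] - 1L, i[e] - 1L))

  nxt <- new.env(hash = TRUE, size = length(from))
  for (k in seq_along(from)) {
    ky <- as.character(from[k])
    nxt[[ky]] <- c(nxt[[ky]], to[k])
  }
  start <- from[1]
  path <- integer(length(from) + 1L)
  path[1] <- start
  cur <- start
  n_used <- 1L
  prev <- NA_integer_
  repeat {
    cand <- nxt[[as.character(cur)]]
    if (length(cand) > 1) {
      # at a pinch vertex prefer the turn that keeps the walk locally convex;
      # take the first candidate not returning straight to the previous vertex
      cand <- cand[cand != prev]
    }
    nx <- cand[1]
    # consume it
    rest <- nxt[[as.character(cur)]]
    nxt[[as.character(cur)]] <- rest[-match(nx, rest)]
    n_used <- n_used + 1L
    path[n_used] <- nx
    prev <- cur
    cur <- nx
    if (cur == start) break
    if (n_used > length(from) + 1L) stop("outline tracing failed to close")
  }
  path <- path[seq_len(n_used - 1L)]  # open ring
  b <- path %% (nr + 2L)
  a <- (path - b) %/% (nr + 2L)
  xy <- cbind(x0 + (a - 1L) * s, y0 + (b - 1L) * s)
  # drop collinear intermediate vertices to keep the ring compact
  n <- nrow(xy)
  keep <- rep(TRUE, n)
  for (v in seq_len(n)) {
    p <- xy[if (v == 1) n else v - 1L, ]
    q <- xy[v, ]
    r2 <- xy[if (v == n) 1L else v + 1L, ]
    if ((q[1] - p[1]) * (r2[2] - p[2]) == (q[2] - p[2]) * (r2[1] - p[1]))
      keep[v] <- FALSE
  }
  lake_polygon(xy[keep, , drop = FALSE])
}

# ---- seed plumbing ----------------------------------------------------------

# Stable child seed from (seed, label); keeps results independent of call
# order across modules. Kept below 2^31.
.derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  # double-precision modular arithmetic: exact below 2^53, result < 2^31
  as.integer((as.numeric(seed) * 7919 + h %% 104729) %% 2147483647)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
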