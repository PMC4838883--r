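# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env()

fixture_lake <- function() {
  if (is.null(.fixture_env$lake))
    .fixture_env$lake <- make_lake(lake_spec(cell_size = 10))
  .fixture_env$lake
}

fixture_calendar <- function() {
  if (is.null(.fixture_env$cal))
    .fixture_env$cal <- build_calendar(74.5, 19.0, as.Date("2009-08-25"),
                                       as.Date("2010-09-10"))
  .fixture_env$cal
}

# a small flat-bottomed square lake built directly: uniform depth, square
# boundary; handy when the test needs exact control of the geometry
flat_lake <- function(depth = 20, n = 20, cell = 10) {
  m <- matrix(depth, n, n)
  bathy <- bathy_grid(0, 0, cell, m)
  poly <- lake_polygon(rbind(c(0, 0), c(n * cell, 0),
                             c(n * cell, n * cell), c(0, n * cell)))
  list(bathy = bathy, polygon = poly)
}

make_fixes <- function(fish_id, t, x, y, tag_depth = 1, err = 1) {
  position_fixes(fish_id, t, x, y,
                 rep_len(tag_depth, length(x)), rep_len(err, length(x)))
}

utc <- function(s) as.POSIXct(s, tz = "UTC")
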