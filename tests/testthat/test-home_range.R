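t0 <- as.POSIXct("2009-09-05 00:00:00", tz = "UTC")

test_that("largest-remainder quotas are proportional, capped and exact", {
  # shares (0.5, 0.25, 0.25) of n = 54: raw (27, 13.5, 13.5); floors sum to
  # 53 and the first tied remainder (stratum order) takes the extra seat
  q <- largest_remainder_quota(c(100, 50, 50), 54)
  expect_equal(sum(q), 54)
  expect_equal(q, c(27, 14, 13))
  # a small stratum keeps its proportional share
  q2 <- largest_remainder_quota(c(4, 50, 50), 54)
  expect_equal(sum(q2), 54)
  expect_equal(q2, c(2, 26, 26))
  # a stratum capped below its quota hands the shortfall to the others
  q3 <- largest_remainder_quota(c(1, 99), 99)
  expect_equal(q3, c(1, 98))
  q4 <- largest_remainder_quota(c(2, 8, 8), 17)
  expect_equal(sum(q4), 17)
  expect_lte(q4[1], 2)
  # fewer available than requested: everything is taken
  expect_equal(sum(largest_remainder_quota(c(10, 12, 8), 54)), 30)
})

test_that("stratified subsampling is proportional and reproducible", {
  cal <- fixture_calendar()
  n <- 600
  fx <- make_fixes("A", t0 + (0:(n - 1)) * 4800,
                   x = rnorm(n, 0, 50), y = rnorm(n, 0, 50))
  s1 <- stratified_subsample(fx, cal, 54, seed = 5)
  expect_equal(nrow(s1$sample), 54)
  expect_equal(sum(s1$strata$quota), 54)
  expect_false(s1$under_sampled)
  # quotas proportional to availability (largest remainder: within 1)
  expected <- 54 * s1$strata$available / sum(s1$strata$available)
  expect_true(all(abs(s1$strata$quota - expected) <= 1))
  s2 <- stratified_subsample(fx, cal, 54, seed = 5)
  expect_identical(s1$sample, s2$sample)

  # fewer positions than the target: all selected, flagged
  s3 <- stratified_subsample(fx[1:30, ], cal, 54, seed = 5)
  expect_equal(nrow(s3$sample), 30)
  expect_true(s3$under_sampled)
})

test_that("the kernel UD integrates to one and matches closed forms", {
  # single point with fixed h: the UD is the kernel itself and its K95 is a
  # circle of radius h * sqrt(2 ln 20)
  ud <- suppressWarnings(kernel_ud(rep(0, 5), rep(0, 5), bandwidth = 20,
                                   cell = 2))
  expect_equal(sum(ud$density) * ud$cell^2, 1, tolerance = 1e-9)
  expect_equal(ud$raw_mass, 1, tolerance = 1e-3)
  a95 <- isopleth_area(ud, 0.95)
  expect_lt(abs(a95 - pi * (20 * sqrt(2 * log(20)))^2) /
              (pi * (20 * sqrt(2 * log(20)))^2), 0.03)

  # two distant points: two symmetric modes of equal mass
  ud2 <- kernel_ud(c(rep(-300, 3), rep(300, 3)), rep(0, 6), bandwidth = 10,
                   cell = 2)
  left <- sum(ud2$density[, ud2$gx < 0]) * ud2$cell^2
  expect_equal(left, 0.5, tolerance = 1e-6)

  # href follows sigma_hat * n^(-1/6)
  set.seed(2)
  x <- rnorm(200, 0, 50); y <- rnorm(200, 0, 50)
  ud3 <- kernel_ud(x, y)
  expect_equal(ud3$h, sqrt((var(x) + var(y)) / 2) * 200^(-1 / 6),
               tolerance = 1e-12)

  # degenerate spread falls back to the minimum bandwidth with a warning
  expect_warning(kernel_ud(rep(1, 6), rep(1, 6)), "degenerate")

  expect_error(kernel_ud(1:3, 1:3), "at least 5")
})

test_that("the UD matches an independent KDE on a common grid", {
  skip_if_not_installed("MASS")
  set.seed(4)
  x <- rnorm(100, 0, 40); y <- rnorm(100, 0, 40)
  h <- 15
  ud <- kernel_ud(x, y, bandwidth = h, cell = 5)
  ref <- MASS::kde2d(x, y, h = c(4 * h, 4 * h),  # kde2d quarters its h
                     n = c(length(ud$gx), length(ud$gy)),
                     lims = c(range(ud$gx), range(ud$gy)))
  mine <- t(ud$density)       # kde2d returns z[x, y]
  expect_equal(mine / sum(mine), ref$z / sum(ref$z), tolerance = 1e-6)
})

test_that("isopleths nest and grow toward the full support", {
  set.seed(9)
  ud <- kernel_ud(rnorm(60, 0, 30), rnorm(60, 0, 30), bandwidth = 15)
  a50 <- isopleth_area(ud, 0.50)
  a95 <- isopleth_area(ud, 0.95)
  a999 <- isopleth_area(ud, 0.999)
  expect_true(a50 <= a95 && a95 <= a999)
  full <- length(ud$gx) * length(ud$gy) * ud$cell^2
  expect_lte(a999, full)
  expect_gt(a999 / a95, 1)
})

test_that("clipping to the lake removes only outside area", {
  # isopleth wholly inside a huge polygon: unchanged
  big <- lake_polygon(rbind(c(-5000, -5000), c(5000, -5000),
                            c(5000, 5000), c(-5000, 5000)))
  ud <- suppressWarnings(kernel_ud(rep(0, 6), rep(0, 6), bandwidth = 20,
                                   cell = 2))
  cl <- clip_to_lake(ud, 0.95, big)
  expect_false(cl$clipped)
  expect_equal(cl$area_m2, cl$unclipped_m2)

  # shoreline through the kernel centre: about half the area survives
  half <- lake_polygon(rbind(c(0, -5000), c(5000, -5000),
                             c(5000, 5000), c(0, 5000)))
  cl2 <- clip_to_lake(ud, 0.95, half)
  expect_true(cl2$clipped)
  expect_lt(abs(cl2$area_m2 / cl2$unclipped_m2 - 0.5), 0.05)

  # disjoint polygon: nothing left
  far <- lake_polygon(rbind(c(9000, 9000), c(9100, 9000), c(9100, 9100),
                            c(9000, 9100)))
  expect_equal(clip_to_lake(ud, 0.95, far)$area_m2, 0)
  # clipping never increases area
  expect_lte(cl2$area_m2, cl2$unclipped_m2)
})

test_that("incremental area analysis finds the asymptote", {
  # identical repeated positions: flat curve, asymptote at the minimum k
  res <- suppressWarnings(incremental_area(rep(0, 20), rep(0, 20)))
  expect_equal(res$asymptote_k, 5)
  expect_equal(length(unique(res$curve$area_m2)), 1)
  expect_error(incremental_area(1:4, 1:4), "at least 5")

  # uniform-on-disc points: the curve stabilises within the sample
  set.seed(21)
  n <- 54
  r <- 100 * sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
  res2 <- incremental_area(r * cos(a), r * sin(a), bandwidth = 20)
  expect_false(is.na(res2$asymptote_k))
  expect_lte(res2$asymptote_k, 54)
  # area roughly non-decreasing overall
  expect_gt(tail(res2$curve$area_m2, 1), res2$curve$area_m2[1] * 0.8)
})

test_that("monthly home ranges nest, clip and reproduce", {
  lk <- fixture_lake()
  cal <- fixture_calendar()
  ph <- list(phenotype_spec("Littoral", littoral_affinity = 0.5,
                            step_speed_mean = 0.06, depth_target = 6),
             phenotype_spec("Pelagic", littoral_affinity = 0.1,
                            step_speed_mean = 0.06, depth_target = 12))
  co <- simulate_cohort(lk, ph, c(1, 1), utc("2009-09-01 00:00:00"),
                        days = 59, seed = 6)
  pc <- pipeline_config()
  hr <- monthly_home_ranges(co$fixes, cal, lk$polygon, pc, seed = 2)
  expect_equal(nrow(hr), 4)  # 2 fish x 2 months
  expect_true(all(hr$K50_ha <= hr$K95_ha))
  expect_true(all(hr$K95_ha > 0))
  expect_true(all(hr$n_used <= pc$homerange_sample_n))
  hr2 <- monthly_home_ranges(co$fixes, cal, lk$polygon, pc, seed = 2)
  expect_identical(hr, hr2)

  # fish-months with fewer than 5 positions are skipped and logged
  few <- co$fixes[1:3, ]
  few$fish_id <- "Z01"
  hr3 <- monthly_home_ranges(rbind(co$fixes, few), cal, lk$polygon, pc,
                             seed = 2)
  expect_equal(nrow(hr3), 4)
  expect_match(attr(hr3, "skipped"), "Z01", all = FALSE)
})
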