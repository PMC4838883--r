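t0 <- as.POSIXct("2009-09-05 00:00:00", tz = "UTC")

test_that("zone classification is boundary-inclusive at the littoral limit", {
  g <- bathy_grid(0, 0, 10, matrix(c(8.0, 8.3, 34, 5), 2, 2))
  fx <- make_fixes("A", t0 + (1:3) * 60, x = c(5, 5, 15), y = c(5, 15, 5))
  z <- zone_of(fx, g, 8)
  expect_equal(z, c("littoral", "offshore", "offshore"))
  out <- make_fixes("A", t0, x = 100, y = 100)
  expect_error(zone_of(out, g, 8), "missing bathymetry")
})

test_that("zone availability covers degenerate and realistic basins", {
  expect_equal(zone_availability(flat_lake(5)$bathy),
               c(p_littoral = 1, p_offshore = 0))
  expect_equal(zone_availability(flat_lake(20)$bathy),
               c(p_littoral = 0, p_offshore = 1))
  lk <- fixture_lake()
  p <- zone_availability(lk$bathy)
  expect_equal(sum(p), 1)
  expect_lt(abs(p[["p_littoral"]] - 0.225), 0.02)
})

test_that("monthly use percentages follow the position counts", {
  g <- bathy_grid(0, 0, 10, matrix(c(5, 5, 20, 20), 2, 2, byrow = TRUE))
  # 3 littoral (y < 10) + 1 offshore (y > 10) in one month
  fx <- make_fixes("A", t0 + (1:4) * 3600,
                   x = c(5, 15, 5, 5), y = c(5, 5, 5, 15))
  u <- monthly_use(fx, g)
  expect_equal(nrow(u), 1)
  expect_equal(u$pct_littoral, 75)
  expect_equal(u$pct_offshore, 25)
  expect_equal(u$n_positions, 4)

  all_litt <- make_fixes("A", t0 + (1:10) * 3600, x = rep(5, 10), y = rep(5, 10))
  u2 <- monthly_use(all_litt, g)
  expect_equal(u2$pct_littoral, 100)
  expect_equal(u2$pct_offshore, 0)
})

test_that("estimated monthly use recovers the simulator's true occupancy", {
  lk <- fixture_lake()
  ph <- phenotype_spec("A", littoral_affinity = 0.62, step_speed_mean = 0.06,
                       depth_target = 4, depth_sd = 2)
  tr <- simulate_track(lk, ph, t0, days = 35, seed = 17)
  # noiseless observation isolates the occupancy estimator from QC effects
  fx <- observe_track(tr, telemetry_spec(detection_prob = 1,
                                         position_error_sd = 0,
                                         error_geometry_factor = 0),
                      seed = 17)
  u <- monthly_use(fx, lk$bathy)
  m <- merge(u, tr$monthly_littoral, by = "month")
  m <- m[m$n_positions >= 400, ]  # full months only, not edge spillover
  expect_gte(nrow(m), 1)
  expect_true(all(abs(m$pct_littoral - 100 * m$true_littoral_frac) < 5))
})

test_that("density grids conserve percentages on the 25 m^2 lattice", {
  g <- flat_lake(20)$bathy
  fx <- make_fixes("A", t0 + (1:50) * 3600,
                   x = rep(52, 50), y = rep(52, 50))
  d <- density_grid(fx, g, cell_area = 25)
  expect_equal(nrow(d), 1)
  expect_equal(d$pct, 100)
  expect_equal(d$count, 50)

  set.seed(3)
  n <- 10000
  fx2 <- make_fixes("A", t0 + (1:n) * 60,
                    x = runif(n, 0, 200), y = runif(n, 0, 200))
  d2 <- density_grid(fx2, g, cell_area = 25)
  expect_equal(sum(d2$pct), 100, tolerance = 1e-6)
  expect_lt(max(d2$pct), 5)  # 1600 cells: no cell should dominate

  empty <- fx2[0, ]
  expect_equal(nrow(density_grid(empty, g)), 0)
})

test_that("Jacobs D follows its algebra", {
  expect_equal(jacobs_D(0.5, 0.5), 0)
  expect_equal(jacobs_D(1, 0.775), 1)
  # Pelagic littoral use 7.58 % against 22.5 % availability
  expect_equal(jacobs_D(0.0758, 0.225), -0.5595, tolerance = 5e-4)
  expect_error(jacobs_D(0.5, 0), "strictly")
  expect_error(jacobs_D(0.5, 1), "strictly")
  expect_error(jacobs_D(1.2, 0.5), "r must be")

  r <- seq(0, 1, length.out = 100)
  p <- seq(0.01, 0.99, length.out = 100)
  G <- expand.grid(r = r, p = p)
  D <- jacobs_D(G$r, G$p)
  expect_true(all(D >= -1 - 1e-12 & D <= 1 + 1e-12))
  # antisymmetry to 1e-12
  expect_true(all(abs(jacobs_D(1 - G$r, 1 - G$p) + D) < 1e-12))
  # D = -1 iff r = 0; D = 1 iff r = 1
  expect_true(all((abs(D + 1) < 1e-12) == (G$r == 0)))
  expect_true(all((abs(D - 1) < 1e-12) == (G$r == 1)))
  # strict monotonicity in r at fixed p
  for (pp in c(0.1, 0.225, 0.5, 0.9))
    expect_true(all(diff(jacobs_D(r, pp)) > 0))
})

test_that("morph-month selectivity verdicts follow the t interval", {
  use <- data.frame(fish_id = c("a", "b", "c"), month = "2009-09",
                    n_positions = 10,
                    pct_littoral = c(60, 50, 40),
                    pct_offshore = c(40, 50, 60))
  mm <- c(a = "M", b = "M", c = "M")

  # all-neutral fish: individual D all 0 at p = use
  use0 <- transform(use, pct_littoral = 50, pct_offshore = 50)
  j0 <- morph_monthly_selectivity(use0, mm, p = 0.5, habitat = "littoral")
  expect_equal(j0$mean_D, 0)
  expect_equal(j0$verdict, "neutral")

  # D values {0.4, 0.5, 0.6}: textbook t interval 0.5 +/- 4.302653 * 0.1/sqrt(3)
  useD <- use
  # choose availability p so that D(r, p) = r - 0.0...: instead feed pcts
  # whose D values are exactly {0.4, 0.5, 0.6} by inverting D at p = 0.5:
  # D = (r - 0.5) / (0.5 - ... ) -> at p = 0.5, D = (2r - 1) / ... compute:
  r <- c(0.7, 0.75, 0.8)
  expect_equal(jacobs_D(r, 0.5), c(0.4, 0.5, 0.6))
  useD$pct_littoral <- 100 * r
  j <- morph_monthly_selectivity(useD, mm, p = 0.5, habitat = "littoral")
  expect_equal(j$mean_D, 0.5)
  expect_equal(j$ci_low, 0.5 - 4.302653 * sd(c(.4, .5, .6)) / sqrt(3),
               tolerance = 1e-6)
  expect_equal(j$verdict, "preferred")

  # a single fish cannot support a CI
  j1 <- morph_monthly_selectivity(use[1, ], mm[1], p = 0.5,
                                  habitat = "littoral")
  expect_equal(j1$verdict, "ci_unavailable")
  expect_true(is.na(j1$ci_low))
})

test_that("morph-level mean use aggregates fish then months equally", {
  use <- data.frame(fish_id = c("a", "b", "a", "b"),
                    month = c("2009-09", "2009-09", "2009-10", "2009-10"),
                    n_positions = c(10, 1000, 10, 10),
                    pct_littoral = c(20, 40, 60, 80),
                    pct_offshore = c(80, 60, 40, 20))
  out <- morph_monthly_use(use, c(a = "M", b = "M"))
  expect_equal(out$mean_pct_littoral, c(30, 70))  # fish equally weighted
  ann <- attr(out, "annual")
  expect_equal(ann$pct_littoral, 50)              # months equally weighted
})
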